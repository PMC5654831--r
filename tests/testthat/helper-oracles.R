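# Independent oracles and shared fixtures. The oracles deliberately use
# their own constants and brute-force formulations so they cannot share a
# defect with the implementation they check.

# -- mass oracle: plain atom-mass summation over a formula string ----------
# independent literature values (CODATA/AME), entered separately from the
# package's table
ORACLE_ATOM_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                      O = 15.9949146221, P = 30.97376151)

oracle_formula_mass <- function(formula) {
  parts <- regmatches(formula,
                      gregexpr("([A-Z])([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    total <- total + ORACLE_ATOM_MASS[[el]] * if (nchar(n)) as.numeric(n) else 1
  }
  total
}

# -- full multi-element isotope envelope by naive repeated convolution -----
ORACLE_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = c(1)
)

oracle_envelope <- function(counts, kmax = 4) {
  # counts: named integer vector over C,H,N,O,P
  dist <- c(1, rep(0, kmax))
  for (el in names(counts)) {
    single <- rep(0, kmax + 1)
    iso <- ORACLE_ISOTOPES[[el]]
    single[seq_along(iso)] <- iso
    for (rep_i in seq_len(counts[[el]])) {
      nxt <- rep(0, kmax + 1)
      for (a in 0:kmax) for (b in 0:(kmax - a))
        nxt[a + b + 1] <- nxt[a + b + 1] + dist[a + 1] * single[b + 1]
      dist <- nxt
    }
  }
  dist
}

formula_counts <- function(formula) {
  parts <- regmatches(formula, gregexpr("([A-Z])([0-9]*)", formula))[[1]]
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    counts[el] <- counts[el] + if (nchar(n)) as.integer(n) else 1L
  }
  counts
}

# -- brute-force one-way ANOVA and LSD t from raw sums of squares ----------
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  k <- nlevels(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(x)
    length(x) * (mean(x) - grand)^2))
  ss_within <- sum(unlist(lapply(split(values, groups),
                                 function(x) (x - mean(x))^2)))
  df1 <- k - 1; df2 <- n - k
  msb <- ss_between / df1; mse <- ss_within / df2
  f <- msb / mse
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       mse = mse, df1 = df1, df2 = df2)
}

oracle_lsd_t <- function(x1, x0, mse) {
  (mean(x1) - mean(x0)) / sqrt(mse * (1 / length(x1) + 1 / length(x0)))
}

# -- shared expensive fixtures, built once per test run --------------------
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

zero_noise_sim <- function() fixture("zero_noise_sim", function() {
  cc <- cohort_config(strains = c("C57BL/6", "BALB/c"),
                      replicates_per_group = 2, cv = 0, seed = 101)
  simulate_cohort(cc, spectrum_noise_model(noise_sd = 0, envelope = TRUE))
})

zero_noise_conc <- function() fixture("zero_noise_conc", function() {
  sim <- zero_noise_sim()
  suppressWarnings(quantify_cohort(sim$spectra, sim$truth$samples, sim$db,
                                   sim$truth$standards))
})

default_cohort_conc <- function() fixture("default_cohort_conc", function() {
  sim <- simulate_cohort(cohort_config(seed = 11))
  suppressWarnings(quantify_cohort(sim$spectra, sim$truth$samples, sim$db,
                                   sim$truth$standards))
})

null_screen <- function() fixture("null_screen", function() {
  # complete null: 1000 lognormal species, identical means in all 10
  # strain-by-diet cells, n = 4, CV 0.2
  set.seed(42)
  strains <- c("C57BL/6", "129X1", "BALB/c", "DBA/2", "FVB/N")
  samples <- expand.grid(rep = 1:4, diet = c("CHOW", "HFD"),
                         strain = strains, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("N%02d", seq_len(nrow(samples)))
  n_species <- 1000
  sdlog <- sqrt(log(1 + 0.2^2))
  conc <- do.call(rbind, lapply(seq_len(n_species), function(s) {
    data.frame(sample_id = samples$sample_id, strain = samples$strain,
               diet = samples$diet, species = sprintf("NULL %04d:0", s),
               class = "PC", level = "sum",
               concentration = stats::rlnorm(nrow(samples), -sdlog^2 / 2,
                                             sdlog),
               resolved = FALSE, stringsAsFactors = FALSE)
  }))
  suppressMessages(diet_screen(conc))
})

# minimal concentration table builder
conc_row <- function(sample_id, species, concentration, strain = "A",
                     diet = "CHOW", level = "molecular", resolved = TRUE) {
  cls <- parse_shorthand(species)$lipid_class
  data.frame(sample_id = sample_id, strain = strain, diet = diet,
             species = species, class = cls, level = level,
             concentration = concentration, resolved = resolved,
             stringsAsFactors = FALSE)
}
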