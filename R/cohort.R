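# Synthetic cohorts: ground-truth concentrations for a multi-strain,
# two-diet design with the diet-effect structure of the muscle study, and
# per-sample synthetic scan peak lists with isotope envelopes, internal
# standards and additive noise.

.DEFAULT_STRAINS <- c("C57BL/6", "129X1", "BALB/c", "DBA/2", "FVB/N")

#' Default ground-truth species means (CHOW diet, nmol/mg tissue)
#'
#' A compact muscle lipidome: the most abundant TAG, PC and PE species of
#' the target tissue with class totals anchored to the reference class-total
#' fixture (TAG 7.81, PC 11.27, PE 3.15 nmol/mg, ...). Double-PUFA
#' phospholipids are a small fraction of the phospholipid pool (about 1.9%
#' of 15.56 nmol/mg).
#'
#' @return A data.frame with columns `species` and `mean_nmol_mg`.
#' @export
default_species_means <- function() {
  tab <- c(
    "TAG 50:1" = 0.70, "TAG 50:2" = 0.80, "TAG 50:3" = 0.60,
    "TAG 52:2" = 1.00, "TAG 52:3" = 1.10, "TAG 52:4" = 0.80,
    "TAG 54:3" = 1.00, "TAG 54:4" = 0.96, "TAG 54:5" = 0.85,
    "DAG 34:1" = 0.55, "DAG 36:2" = 0.45, "DAG 36:4" = 0.35,
    "DAG 38:4" = 0.20,
    "CER 18:0" = 0.045, "CER 16:0" = 0.008, "CER 20:0" = 0.003,
    "CER 22:0" = 0.003, "CER 24:0" = 0.004, "CER 24:1" = 0.004,
    "CER 18:1" = 0.001, "CER 26:0" = 0.001, "CER 26:1" = 0.001,
    "SM 18:0" = 0.12, "SM 16:0" = 0.08, "SM 24:1" = 0.06, "SM 19:0" = 0.02,
    "CE 16:0" = 0.02, "CE 18:1" = 0.035, "CE 18:2" = 0.025,
    "PC 16:0/18:1" = 2.64, "PC 16:0/18:2" = 2.00, "PC 16:0/20:4" = 1.60,
    "PC 16:0/22:6" = 1.80, "PC 18:0/20:4" = 1.00, "PC 18:0/22:6" = 0.80,
    "PC 16:0/16:0" = 0.50, "PC 18:1/18:2" = 0.40, "PC 16:1/22:6" = 0.12,
    "PC 18:1/22:6" = 0.15, "PC 16:0/22:5" = 0.10, "PC 18:0/22:5" = 0.02,
    "PC 18:2/22:6" = 0.06, "PC 18:2/20:4" = 0.05, "PC 20:4/22:6" = 0.03,
    "PC-O 34:1" = 0.16, "PC-O 36:4" = 0.12,
    "PE 18:0/20:4" = 0.97, "PE 16:0/22:6" = 0.76, "PE 18:0/22:6" = 0.70,
    "PE 16:0/18:1" = 0.32, "PE 18:1/18:2" = 0.25, "PE 18:2/20:4" = 0.09,
    "PE 20:4/22:6" = 0.06,
    "PE-O 34:2" = 0.20, "PE-O 36:4" = 0.18, "PE-O 38:5" = 0.15,
    "PS 18:0/18:1" = 0.13, "PS 18:0/20:4" = 0.08, "PS 18:0/22:6" = 0.12
  )
  data.frame(species = names(tab), mean_nmol_mg = unname(tab),
             stringsAsFactors = FALSE)
}

#' Cohort configuration
#'
#' Defines the study design the generator emulates: five inbred strains on
#' two diets with four replicates per strain-by-diet cell and 25 mg of tissue
#' per sample. The default effect model encodes the study's diet-response
#' structure: the high-fat diet doubles every TAG species mean, leaves DAG,
#' CER and SM unchanged, and reduces double-PUFA phospholipid means by the
#' factor `double_pufa_hfd_multiplier` in every strain except the protected
#' one (BALB/c). Replicate variation is lognormal with coefficient of
#' variation `cv`, so concentrations stay positive and log transforms are
#' natural downstream.
#'
#' @param strains Strain labels.
#' @param diets Diet labels; the second is the intervention diet.
#' @param replicates_per_group Samples per strain-by-diet cell (>= 2).
#' @param seed Integer seed; fully determines generator output.
#' @param cv Lognormal coefficient of variation of replicate concentrations.
#' @param tissue_mass_mg Tissue mass per sample.
#' @param species_means CHOW means, as from [default_species_means()].
#' @param tag_hfd_multiplier HFD multiplier on TAG species means.
#' @param double_pufa_hfd_multiplier HFD multiplier on double-PUFA
#'   phospholipid means in unprotected strains.
#' @param protected_strain Strain whose double-PUFA species do not respond.
#' @param standards Internal-standard table
#'   (see [default_internal_standards()]).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(strains = .DEFAULT_STRAINS,
                          diets = c("CHOW", "HFD"),
                          replicates_per_group = 4L,
                          seed = 1L,
                          cv = 0.15,
                          tissue_mass_mg = 25,
                          species_means = default_species_means(),
                          tag_hfd_multiplier = 2,
                          double_pufa_hfd_multiplier = 0.6,
                          protected_strain = "BALB/c",
                          standards = default_internal_standards()) {
  if (replicates_per_group < 2)
    stop("replicates_per_group must be >= 2 (group statistics need ",
         "at least two samples)")
  if (any(species_means$mean_nmol_mg <= 0))
    stop("all species means must be positive")
  if (cv < 0) stop("cv must be >= 0")
  structure(list(
    strains = strains, diets = diets,
    replicates_per_group = as.integer(replicates_per_group),
    seed = as.integer(seed), cv = cv, tissue_mass_mg = tissue_mass_mg,
    species_means = species_means,
    tag_hfd_multiplier = tag_hfd_multiplier,
    double_pufa_hfd_multiplier = double_pufa_hfd_multiplier,
    protected_strain = protected_strain,
    standards = standards
  ), class = "cohort_config")
}

# double-PUFA flag for the effect model: molecular diacyl PL with two
# PUFA chains
.is_double_pufa <- function(species_names) {
  vapply(species_names, function(nm) {
    sp <- parse_shorthand(nm)
    if (sp$level != "molecular" || !sp$lipid_class %in% c("PC", "PE", "PS"))
      return(FALSE)
    count_pufa_chains(sp) == 2L
  }, logical(1), USE.NAMES = FALSE)
}

#' Generate ground-truth cohort concentrations
#'
#' Draws per-sample species concentrations as independent lognormals around
#' the effect-model means (`E[conc] = mean`, CV as configured). Setting
#' `cv = 0` makes every replicate equal its group mean exactly.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_truth` with elements `samples` (sample
#'   table: id, strain, diet, tissue mass), `truth` (long table: sample_id,
#'   species, class, concentration in nmol/mg) and `standards`.
#' @examples
#' truth <- generate_cohort_truth(cohort_config(seed = 1))
#' nrow(truth$samples)  # 5 strains x 2 diets x 4 replicates = 40
#' @export
generate_cohort_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  grid <- expand.grid(rep = seq_len(config$replicates_per_group),
                      diet = config$diets, strain = config$strains,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(nrow(grid))),
    strain = grid$strain, diet = grid$diet,
    tissue_mass_mg = config$tissue_mass_mg,
    stringsAsFactors = FALSE
  )
  sm <- config$species_means
  sp_class <- vapply(sm$species,
                     function(nm) parse_shorthand(nm)$lipid_class,
                     character(1), USE.NAMES = FALSE)
  dp <- .is_double_pufa(sm$species)
  sdlog <- sqrt(log(1 + config$cv^2))
  hfd <- config$diets[2]
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    mult <- rep(1, nrow(sm))
    if (samples$diet[i] == hfd) {
      mult[sp_class == "TAG"] <- config$tag_hfd_multiplier
      if (samples$strain[i] != config$protected_strain)
        mult[dp] <- config$double_pufa_hfd_multiplier
    }
    mu <- sm$mean_nmol_mg * mult
    conc <- if (config$cv == 0) mu else
      stats::rlnorm(nrow(sm), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    data.frame(sample_id = samples$sample_id[i], species = sm$species,
               class = sp_class, concentration = conc,
               stringsAsFactors = FALSE)
  })
  structure(list(samples = samples, truth = do.call(rbind, rows),
                 standards = config$standards, config = config),
            class = "cohort_truth")
}

#' Spectrum noise model
#'
#' Controls how ground truth is turned into peak lists: the per-class
#' intensity response (arbitrary units per nmol), the negative-mode response,
#' a baseline of spurious low-intensity peaks with additive Gaussian noise,
#' and the isotope envelope (carbon binomial by default, full multi-element
#' convolution as the exact alternative).
#'
#' @param response Intensity per nmol in positive-mode channels; a scalar or
#'   a named vector keyed by class.
#' @param response_neg Intensity per nmol in fatty-acyl precursor channels.
#' @param baseline Mean intensity of baseline peaks.
#' @param noise_sd Additive noise standard deviation; 0 disables noise and
#'   baseline peaks entirely.
#' @param n_baseline_peaks Baseline peaks per channel when noise is active.
#' @param envelope Logical; emit M+0..M+4 isotopologue peaks.
#' @param envelope_model `"binomial"` or `"convolution"`.
#' @param p13c 13C abundance for the binomial envelope.
#' @return A list of class `noise_model`.
#' @export
spectrum_noise_model <- function(response = 2000, response_neg = 1000,
                                 baseline = 6, noise_sd = 2,
                                 n_baseline_peaks = 150L,
                                 envelope = TRUE,
                                 envelope_model = c("binomial", "convolution"),
                                 p13c = 0.0107) {
  if (any(response <= 0) || response_neg <= 0)
    stop("response factors must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(response = response, response_neg = response_neg,
                 baseline = baseline, noise_sd = noise_sd,
                 n_baseline_peaks = as.integer(n_baseline_peaks),
                 envelope = envelope,
                 envelope_model = match.arg(envelope_model), p13c = p13c),
            class = "noise_model")
}

.class_response <- function(noise, cls) {
  if (length(noise$response) == 1L && is.null(names(noise$response)))
    return(unname(noise$response))
  if (!cls %in% names(noise$response))
    stop("no response factor for class ", cls)
  unname(noise$response[[cls]])
}

.parse_formula <- function(formula) {
  m <- gregexpr("([CHNOP])(\\d*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([CHNOP])(\\d*)", formula))[[1]]
  counts <- stats::setNames(rep(0L, length(ELEMENTS)), ELEMENTS)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    counts[el] <- counts[el] + if (nchar(n)) as.integer(n) else 1L
  }
  composition(counts[["C"]], counts[["H"]], counts[["N"]], counts[["O"]],
              counts[["P"]])
}

.envelope_for_row <- function(db_row, noise) {
  if (!noise$envelope) return(1)
  if (noise$envelope_model == "binomial")
    stats::dbinom(0:4, size = db_row$n_carbon_atoms, prob = noise$p13c)
  else
    isotope_envelope(.parse_formula(db_row$formula), kmax = 4L,
                     model = "convolution")
}

# merge centroids closer than `tol` Th (unit-resolution instruments cannot
# separate a species' M+2 from the monoisotopic peak of the neighbour with
# one fewer double bond, 0.009 Th away)
.merge_peaks <- function(mz, intensity, tol = 0.2) {
  if (length(mz) == 0) return(data.frame(mz = numeric(), intensity = numeric()))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  grp <- cumsum(c(TRUE, diff(mz) > tol))
  data.frame(
    mz = vapply(split(seq_along(mz), grp), function(i)
      sum(mz[i] * intensity[i]) / max(sum(intensity[i]), .Machine$double.xmin),
      numeric(1)),
    intensity = vapply(split(intensity, grp), sum, numeric(1))
  )
}

.finish_channel <- function(mz, intensity, noise, polarity, scan_type,
                            extract) {
  pk <- .merge_peaks(mz, intensity)
  if (noise$noise_sd > 0) {
    pk$intensity <- pmax(pk$intensity +
                           stats::rnorm(nrow(pk), 0, noise$noise_sd), 0)
    if (noise$n_baseline_peaks > 0) {
      lo <- if (nrow(pk)) min(pk$mz) - 20 else 400
      hi <- if (nrow(pk)) max(pk$mz) + 20 else 1000
      bl <- data.frame(
        mz = stats::runif(noise$n_baseline_peaks, lo, hi),
        intensity = abs(stats::rnorm(noise$n_baseline_peaks, noise$baseline,
                                     noise$noise_sd))
      )
      pk <- rbind(pk, bl)
    }
    pk$snr <- pk$intensity / noise$noise_sd
  } else {
    pk$snr <- ifelse(pk$intensity > 0, Inf, 0)
  }
  pk <- pk[order(pk$mz), ]
  rownames(pk) <- NULL
  scan_spectrum(pk, polarity = polarity, scan_type = scan_type,
                extract = extract)
}

#' Synthesize per-sample scan spectra from ground truth
#'
#' For each class' quantification channel, emits peaks at the database target
#' m/z with intensity = response x amount (nmol), expanded over the M+0..M+4
#' isotope envelope when enabled; internal standards appear in their class
#' channels at their spiked amounts; ether-PE species are emitted at 1/3.45
#' of the diacyl response in the neutral-loss channel (they do not produce
#' the head-group fragment as efficiently). Negative-mode fatty-acyl
#' precursor channels carry one peak per molecular phospholipid containing
#' the chain, proportional to amount (twice for a repeated chain). Peaks
#' closer than 0.2 Th are merged, additive noise and baseline peaks are
#' applied, and an s/n column is attached.
#'
#' Randomness (noise draws) uses the current RNG state; [simulate_cohort()]
#' seeds it from the cohort config for byte-identical reruns.
#'
#' @param truth A `cohort_truth` from [generate_cohort_truth()].
#' @param noise A [spectrum_noise_model()].
#' @param db A `species_db`; every truth species must be present.
#' @param ether_pe_response Response suppression factor for ether-PE in the
#'   neutral-loss channel (emitted at `1/ether_pe_response`).
#' @return Named list (by sample id) of named lists of `scan_spectrum`
#'   objects (by channel id `"<scan_type>.<extract>"` or `"fa_<C:D>.total"`).
#' @export
synthesize_spectra <- function(truth, noise = spectrum_noise_model(), db,
                               ether_pe_response = pipeline_defaults()$ether_pe_factor) {
  stopifnot(inherits(truth, "cohort_truth"))
  missing <- setdiff(unique(c(truth$truth$species, truth$standards$species)),
                     db$name)
  if (length(missing))
    stop("species missing from database: ", paste(missing, collapse = ", "))
  db_idx <- stats::setNames(seq_len(nrow(db)), db$name)
  classes <- lipid_classes()
  is_tab <- truth$standards
  is_species <- unique(is_tab[, c("species", "amount_nmol")])
  out <- vector("list", nrow(truth$samples))
  names(out) <- truth$samples$sample_id
  for (i in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[i]
    tr <- truth$truth[truth$truth$sample_id == sid, ]
    amounts <- stats::setNames(tr$concentration * truth$samples$tissue_mass_mg[i],
                               tr$species)
    amounts <- c(amounts, stats::setNames(is_species$amount_nmol,
                                          is_species$species))
    channels <- list()
    # positive-mode class channels
    for (ci in seq_len(nrow(classes))) {
      ch_classes <- classes$class[classes$scan_type == classes$scan_type[ci] &
                                    classes$extract == classes$extract[ci]]
      chan_id <- paste(classes$scan_type[ci], classes$extract[ci], sep = ".")
      if (!is.null(channels[[chan_id]])) next
      mzs <- numeric(); ints <- numeric()
      for (nm in names(amounts)) {
        row <- db[db_idx[[nm]], ]
        if (!row$class %in% ch_classes) next
        resp <- .class_response(noise, row$class)
        if (row$class == "PE-O") resp <- resp / ether_pe_response
        env <- .envelope_for_row(row, noise)
        k <- seq_along(env) - 1L
        mzs <- c(mzs, row$mz_quant + k * .C13_C12_DIFF)
        ints <- c(ints, amounts[[nm]] * resp * env)
      }
      channels[[chan_id]] <- .finish_channel(
        mzs, ints, noise, "+", classes$scan_type[ci], classes$extract[ci])
    }
    # negative-mode fatty-acyl precursor channels
    mol <- db[db_idx[names(amounts)], ]
    mol <- mol[mol$level == "molecular" & mol$class %in% c("PC", "PE", "PS"), ]
    if (nrow(mol)) {
      chain_lists <- strsplit(mol$chains, "/", fixed = TRUE)
      all_chains <- sort(unique(unlist(chain_lists)))
      for (ch in all_chains) {
        n_occ <- vapply(chain_lists, function(x) sum(x == ch), integer(1))
        sel <- n_occ > 0
        channels[[paste0("fa_", ch, ".total")]] <- .finish_channel(
          mol$mz_neg[sel],
          amounts[mol$name[sel]] * noise$response_neg * n_occ[sel],
          noise, "-", paste0("fa_", ch), "total")
      }
    }
    out[[sid]] <- channels
  }
  out
}

#' Simulate a full cohort (truth + spectra), deterministically
#'
#' @param config A [cohort_config()]; its seed determines all randomness.
#' @param noise A [spectrum_noise_model()].
#' @param db A `species_db`; defaults to the standard database with the
#'   config's internal standards appended.
#' @return A list of class `cohort_sim` with elements `truth`, `spectra`,
#'   `db`, `noise`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            noise = spectrum_noise_model(),
                            db = NULL) {
  if (is.null(db))
    db <- build_species_database(standards = config$standards)
  truth <- generate_cohort_truth(config)  # seeds the RNG
  spectra <- synthesize_spectra(truth, noise, db)
  structure(list(truth = truth, spectra = spectra, db = db, noise = noise),
            class = "cohort_sim")
}
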