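# Log transform, omnibus ANOVA, the rank diagnostic, protected LSD and
# directional counts, checked against brute-force sums of squares and
# stock implementations.

test_that("log transform handles zeros and all-zero species", {
  m <- matrix(c(exp(1), exp(2), exp(3), 0, 2, 4, 0, 0, 0), nrow = 3,
              byrow = TRUE, dimnames = list(c("a", "b", "zz"), NULL))
  expect_message(lt <- log_transform(m), "all-zero")
  expect_equal(lt$dropped, "zz")
  expect_equal(unname(lt$log_mat["a", ]), c(1, 2, 3))  # natural log
  expect_equal(unname(exp(lt$log_mat["b", 1])), 1)  # 0 -> half of min(2,4)
  expect_equal(lt$replaced[["b"]], 1L)
  expect_error(log_transform(matrix(-1)), ">= 0")
})

test_that("omnibus ANOVA matches brute-force sums of squares", {
  # textbook two-cell instance
  v <- c(1, 2, 3, 4, 2, 3, 4, 5)
  g <- rep(c("a", "b"), each = 4)
  a <- omnibus_anova(v, g)
  o <- oracle_anova(v, g)
  expect_equal(a$F, o$F, tolerance = 1e-12)
  expect_equal(a$p, o$p, tolerance = 1e-12)
  expect_equal(a$mse, o$mse, tolerance = 1e-12)

  # 25 random small instances, 1e-10 relative agreement
  set.seed(99)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    n <- sample(2:5, 1)
    v <- rnorm(k * n)
    g <- rep(seq_len(k), each = n)
    a <- omnibus_anova(v, g)
    o <- oracle_anova(v, g)
    expect_equal(a$F, o$F, tolerance = 1e-10)
    expect_equal(a$p, o$p, tolerance = 1e-10)
    expect_equal(a$mse, o$mse, tolerance = 1e-10)
  }

  # two-cell special case equals the pooled-variance two-sample t-test
  v <- rnorm(12); g <- rep(c("x", "y"), each = 6)
  a <- omnibus_anova(v, g)
  tt <- t.test(v[g == "x"], v[g == "y"], var.equal = TRUE)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)

  # degenerate zero-variance conventions
  expect_message(a1 <- omnibus_anova(rep(c(1, 1), each = 3),
                                     rep(c("a", "b"), each = 3)), "convention")
  expect_equal(a1$p, 1)
  expect_message(a2 <- omnibus_anova(rep(c(1, 2), each = 3),
                                     rep(c("a", "b"), each = 3)), "convention")
  expect_equal(a2$p, 0)
})

test_that("null ANOVA p values are uniform", {
  set.seed(8)
  cell <- factor(rep(1:10, each = 4))
  p <- replicate(400, omnibus_anova(rlnorm(40, 0, 0.2), cell)$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the rank diagnostic sorts and scales", {
  d <- rank_pvalue_diagnostic(c(a = 0.2, b = 0.05, c = 0.9))
  expect_equal(d$p, c(0.05, 0.2, 0.9))
  expect_equal(d$rank, 1:3)
  expect_equal(d$expected_uniform, (1:3) / 4)
  expect_equal(d$species, c("b", "a", "c"))
  # uniform p values track the diagonal
  set.seed(12)
  p <- runif(500)
  d2 <- rank_pvalue_diagnostic(p)
  expect_lt(max(abs(d2$p - d2$expected_uniform)), 0.1)
  expect_error(rank_pvalue_diagnostic(0.5), "at least two")
})

test_that("protection gates the post-hoc tests", {
  set.seed(30)
  strain <- rep(c("A", "B"), each = 8)
  diet <- rep(rep(c("CHOW", "HFD"), each = 4), 2)
  v <- rnorm(16)
  gated <- protected_lsd(list(p = 0.2, mse = 1, df_within = 12), v, v,
                         strain, diet)
  expect_equal(nrow(gated), 0L)

  # equal group means in one strain: p near 1, direction none
  v2 <- c(1, 2, 3, 4, 1, 2, 3, 4, rnorm(4), rnorm(4, 5))
  cell <- paste(strain, diet)
  a <- omnibus_anova(v2, cell)
  ph <- protected_lsd(a, v2, v2, strain, diet)
  expect_equal(ph$p[ph$strain == "A"], 1, tolerance = 1e-9)
  expect_equal(ph$direction[ph$strain == "A"], "none")

  # LSD t matches the brute-force pooled-error formula on random instances
  set.seed(31)
  for (i in 1:25) {
    v3 <- rnorm(16, mean = rep(c(0, 1.5, 0, 0), each = 4))
    a3 <- omnibus_anova(v3, cell)
    o3 <- oracle_anova(v3, cell)
    ph3 <- protected_lsd(a3, v3, v3, strain, diet, omnibus_alpha = 1.01)
    for (st in c("A", "B")) {
      x1 <- v3[strain == st & diet == "HFD"]
      x0 <- v3[strain == st & diet == "CHOW"]
      expect_equal(ph3$t[ph3$strain == st], oracle_lsd_t(x1, x0, o3$mse),
                   tolerance = 1e-10)
    }
  }
})

test_that("LSD estimates agree with emmeans pairwise contrasts", {
  set.seed(44)
  d <- data.frame(strain = rep(c("A", "B"), each = 8),
                  diet = rep(rep(c("CHOW", "HFD"), each = 4), 2))
  d$y <- rnorm(16) + (d$diet == "HFD") * (d$strain == "A")
  fit <- stats::lm(y ~ interaction(strain, diet), data = d)
  em <- emmeans::emmeans(fit, ~ interaction(strain, diet))
  ctr <- as.data.frame(emmeans::contrast(
    em, method = list(A = c(-1, 0, 1, 0), B = c(0, -1, 0, 1)),
    adjust = "none"))
  a <- omnibus_anova(d$y, paste(d$strain, d$diet))
  ph <- protected_lsd(a, d$y, d$y, d$strain, d$diet, omnibus_alpha = 1.01)
  expect_equal(ph$t[match(c("A", "B"), ph$strain)], ctr$t.ratio,
               tolerance = 1e-8)
  expect_equal(ph$p[match(c("A", "B"), ph$strain)], ctr$p.value,
               tolerance = 1e-8)
})

test_that("directional counts partition by class and strain", {
  ph <- data.frame(
    species = c("TAG 50:1", "TAG 50:2", "TAG 52:3", "TAG 54:4",
                "PC 16:0/22:6"),
    class = c(rep("TAG", 4), "PC"),
    strain = "C57BL/6",
    direction = c(rep("up", 4), "down"),
    significant = TRUE, stringsAsFactors = FALSE)
  cnt <- count_directional_changes(ph, strains = "C57BL/6")
  expect_equal(cnt$n_up[cnt$class == "TAG"], 4L)
  expect_equal(cnt$n_down[cnt$class == "PC"], 1L)
  expect_equal(cnt$n_up[cnt$class == "PC"], 0L)
  expect_equal(sum(cnt$n_up) + sum(cnt$n_down), 5L)
  none <- count_directional_changes(ph[0, ], strains = "C57BL/6")
  expect_true(all(none$n_up == 0 & none$n_down == 0))
})

test_that("a doubled TAG effect is detected in every strain at CV 0.1", {
  cc <- cohort_config(cv = 0.1, seed = 55)
  truth <- generate_cohort_truth(cc)
  conc <- merge(truth$truth, truth$samples, by = "sample_id")
  conc$level <- "sum"; conc$resolved <- FALSE
  scr <- suppressMessages(diet_screen(conc))
  tag_up <- scr$counts[scr$counts$class == "TAG", ]
  expect_true(all(tag_up$n_up == 9L))
  expect_true(all(tag_up$n_down == 0L))
})

test_that("a stronger effect never yields fewer significant calls", {
  counts <- vapply(c(1.3, 2, 3), function(mult) {
    truth <- generate_cohort_truth(cohort_config(seed = 77,
                                                 tag_hfd_multiplier = mult))
    conc <- merge(truth$truth, truth$samples, by = "sample_id")
    conc$level <- "sum"; conc$resolved <- FALSE
    scr <- suppressMessages(diet_screen(conc))
    sum(scr$counts$n_up[scr$counts$class == "TAG"])
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("per-strain ANOVA mode is available and gates per strain", {
  truth <- generate_cohort_truth(cohort_config(cv = 0.1, seed = 56))
  conc <- merge(truth$truth, truth$samples, by = "sample_id")
  conc$level <- "sum"; conc$resolved <- FALSE
  scr <- suppressMessages(diet_screen(conc, anova_mode = "per_strain"))
  tag_up <- scr$counts[scr$counts$class == "TAG", ]
  expect_true(all(tag_up$n_up == 9L))
  expect_s3_class(scr, "diet_screen")
})
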