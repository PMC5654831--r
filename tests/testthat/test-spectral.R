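# Smoothing, s/n filtering, database matching, peak-list I/O and the
# two-stage isotope correction.

make_spec <- function(mz, intensity, snr = NULL, scan_type = "hg184",
                      extract = "total", polarity = "+") {
  pk <- data.frame(mz = mz, intensity = intensity)
  if (!is.null(snr)) pk$snr <- snr
  scan_spectrum(pk, polarity = polarity, scan_type = scan_type,
                extract = extract)
}

test_that("moving-average smoothing behaves at the edges", {
  sp <- make_spec(1:5, c(0, 0, 3, 0, 0))
  expect_equal(smooth_spectrum(sp, 1)$peaks$intensity, c(0, 0, 3, 0, 0))
  expect_equal(smooth_spectrum(sp, 3)$peaks$intensity, c(0, 1, 1, 1, 0))
  const <- make_spec(1:7, rep(2.5, 7))
  expect_equal(smooth_spectrum(const, 5)$peaks$intensity, rep(2.5, 7))
  expect_identical(smooth_spectrum(const, 5)$peaks$mz, const$peaks$mz)
  expect_error(smooth_spectrum(sp, 2), "odd")
})

test_that("the s/n filter is strictly greater-than", {
  sp <- make_spec(c(100, 200, 300), c(5, 10, 10.01) * 7,
                  snr = c(5, 10, 10.01))
  kept <- detect_and_filter(sp, 10)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$snr, 10.01)
  expect_equal(nrow(detect_and_filter(sp, 0.0001)), 3L)
  # all-baseline spectrum: nothing above threshold
  base <- make_spec(1:50, rep(1, 50), snr = rep(0.8, 50))
  expect_equal(nrow(detect_and_filter(base, 10)), 0L)
  expect_equal(nrow(detect_and_filter(make_spec(numeric(0), numeric(0)),
                                      10)), 0L)
})

test_that("s/n is estimated robustly when absent", {
  set.seed(4)
  baseline <- abs(rnorm(200, 5, 1))
  sp <- make_spec(c(seq(400, 599.5, length.out = 200), 700, 710),
                  c(baseline, 500, 400))
  kept <- detect_and_filter(sp, 10)
  expect_setequal(kept$mz, c(700, 710))
  # zero noise scale: every positive peak is kept
  clean <- make_spec(c(1, 2, 3), c(10, 10, 10))
  expect_equal(nrow(detect_and_filter(clean, 10)), 3L)
})

test_that("peaks match to the nearest target; far peaks drop; ties log", {
  db <- build_species_database()
  target <- db$mz_quant[db$name == "PC 16:0/18:1"]  # PC 34:1 sum group
  sp <- make_spec(c(target + 0.2, target + 5), c(100, 50), snr = c(99, 99))
  hits <- match_to_database(sp, db, tol = 0.3)
  expect_equal(hits$target, "PC 34:1")
  expect_equal(hits$raw, 100)

  # equidistant targets resolve toward lower m/z
  db2 <- build_species_database(chain_space = list(
    pl_acyls = c("16:0", "18:1"), ether = NULL, tag = NULL, dag = NULL,
    ce_acyls = NULL, n_acyls = NULL))
  t1 <- db2$mz_quant[db2$name == "PC 16:0/16:0"]
  t2 <- db2$mz_quant[db2$name == "PC 16:0/18:1"]
  mid <- (t1 + t2) / 2
  spm <- make_spec(mid, 10, snr = 99)
  expect_message(hits2 <- match_to_database(spm, db2, tol = 20),
                 "lower-m/z")
  expect_equal(hits2$target, "PC 32:0")
})

test_that("ether species win ambiguous ether/odd-chain masses", {
  db <- build_species_database(chain_space = list(
    pl_acyls = c("15:0", "16:0", "18:1"),
    ether = list(carbons = 34L, double_bonds = 1L),
    tag = NULL, dag = NULL, ce_acyls = NULL, n_acyls = NULL))
  # PC 15:0/18:1 (PC 33:1) and PC-O 34:1 are 0.036 Th apart
  mz_odd <- db$mz_quant[db$name == "PC 15:0/18:1"]
  expect_message(pick <- assign_ether_or_odd(mz_odd, db), "ambiguous")
  expect_equal(pick, "PC-O 34:1")
  # unambiguous even-chain diacyl assigns to itself
  mz_even <- db$mz_quant[db$name == "PC 16:0/18:1"]
  expect_equal(suppressMessages(assign_ether_or_odd(mz_even + 0.29, db)),
               "PC 34:1")
  expect_true(is.na(assign_ether_or_odd(mz_even + 5, db)))
  # the matcher applies the same preference
  sp <- make_spec(mz_odd, 100, snr = 99)
  expect_message(hits <- match_to_database(sp, db, tol = 0.3), "ambiguity")
  expect_equal(hits$target, "PC-O 34:1")
})

test_that("peak-list files round-trip and corrupt lines are located", {
  sp <- make_spec(c(700.1, 701.1), c(10, 20), snr = c(15, 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(sp, path)
  back <- read_peaklist(path, scan_type = "hg184")
  expect_equal(back$peaks, sp$peaks, tolerance = 1e-12)
  writeLines(c("mz\tintensity", "700.1\t10", "oops\t5"), path)
  expect_error(read_peaklist(path), "corrupt peak-list line 3")
})

test_that("isotope correction inverts the envelope", {
  db <- build_species_database()
  row42 <- db[db$name == "PC 16:0/18:1", ]  # 42 carbons
  lone <- data.frame(target = "PC 34:1", class = "PC", channel = "hg184",
                     extract = "total", mz = row42$mz_quant,
                     target_mz = row42$mz_quant, raw = 1000,
                     carbons = 42L, sum_carbons = 34L,
                     sum_double_bonds = 1L, is_standard = FALSE,
                     stringsAsFactors = FALSE)
  out <- isotope_correct(lone)
  f0 <- (1 - 0.0107)^42
  expect_equal(out$corrected, 1000 / f0, tolerance = 1e-12)
  expect_equal(out$corrected, 1571, tolerance = 0.001)

  # a pure-contamination peak one double bond below corrects to zero:
  # with equal carbon counts, raw(i) = a2 * raw(j) is entirely j's M+2
  a2 <- choose(42, 2) * 0.0107^2 * (1 - 0.0107)^40 / f0
  expect_equal(a2, 0.1007, tolerance = 1e-3)
  pair <- rbind(lone, within(lone, {
    target <- "PC 34:0"; sum_double_bonds <- 0L
    mz <- mz + 2.01565; target_mz <- target_mz + 2.01565
    raw <- a2 * 1000
  }))
  out2 <- isotope_correct(pair)
  expect_equal(out2$corrected[out2$target == "PC 34:0"], 0)
  expect_equal(out2$corrected[out2$target == "PC 34:1"], 1000 / f0)

  # disabled correction is the identity
  out3 <- isotope_correct(pair, enabled = FALSE)
  expect_equal(out3$corrected, out3$raw)

  # order independence
  shuffled <- pair[2:1, ]
  out4 <- isotope_correct(shuffled)
  expect_equal(out4$corrected[match(out2$target, out4$target)],
               out2$corrected)
})

test_that("correction recovers envelope-off intensities (convolution oracle)", {
  # species up to 60 carbons, generated with the full multi-element
  # envelope and corrected with the matching model: recovery within 1%
  cs <- list(pl_acyls = NULL, ether = NULL,
             tag = list(carbons = seq(48L, 60L, 2L), double_bonds = 0:5),
             dag = NULL, ce_acyls = NULL, n_acyls = NULL)
  db <- build_species_database(chain_space = cs,
                               standards = data.frame(
                                 class = "TAG", species = "TAG 51:0",
                                 amount_nmol = 2.5))
  means <- data.frame(
    species = c("TAG 50:1", "TAG 52:3", "TAG 54:5", "TAG 56:2", "TAG 58:4",
                "TAG 60:5"),
    mean_nmol_mg = c(0.8, 1.1, 0.9, 0.5, 0.4, 0.3))
  cc <- cohort_config(strains = "A", replicates_per_group = 2, cv = 0,
                      seed = 31, species_means = means,
                      standards = data.frame(class = "TAG",
                                             species = "TAG 51:0",
                                             amount_nmol = 2.5))
  truth <- generate_cohort_truth(cc)
  on_spec <- synthesize_spectra(
    truth, spectrum_noise_model(noise_sd = 0, envelope = TRUE,
                                envelope_model = "convolution"), db)
  off_spec <- synthesize_spectra(
    truth, spectrum_noise_model(noise_sd = 0, envelope = FALSE), db)
  get_corr <- function(spectra, enabled) {
    sp <- spectra[["S01"]][["cls_TAG.total"]]
    sp$peaks <- detect_and_filter(sp, 10)
    ident <- match_to_database(sp, db, 0.3)
    out <- isotope_correct(ident, model = "convolution", db = db,
                           enabled = enabled)
    stats::setNames(out$corrected, out$target)[order(out$target)]
  }
  rec <- get_corr(on_spec, TRUE)
  ref <- get_corr(off_spec, FALSE)
  common <- intersect(names(rec), names(ref))
  expect_setequal(common, c(means$species, "TAG 51:0"))
  expect_equal(rec[common] / ref[common], rep(1, length(common)),
               tolerance = 0.01, ignore_attr = TRUE)

  # the package's convolution envelope matches the brute-force oracle
  for (nm in c("TAG 50:1", "TAG 60:5")) {
    counts <- formula_counts(db$formula[db$name == nm])
    expect_equal(
      isotope_envelope(do.call(composition, as.list(counts)),
                       model = "convolution"),
      oracle_envelope(counts), tolerance = 1e-10)
  }
})
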