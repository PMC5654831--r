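# Internal-standard quantification, the ether-PE factor, molecular-species
# resolution and its conservation/linearity properties.

ident_row <- function(target, class, corrected, is_standard = FALSE) {
  data.frame(target = target, class = class, channel = "x",
             extract = "total", mz = 0, target_mz = 0, raw = corrected,
             carbons = 40L, sum_carbons = 34L, sum_double_bonds = 1L,
             is_standard = is_standard, corrected = corrected,
             stringsAsFactors = FALSE)
}

test_that("concentrations scale by the internal-standard ratio", {
  ident <- rbind(ident_row("PC 34:1", "PC", 500),
                 ident_row("PC 26:0", "PC", 500, is_standard = TRUE))
  is_rec <- list(class = "PC", species = "PC 13:0/13:0", amount_nmol = 0.5)
  q <- quantify_class(ident, is_rec, tissue_mass = 25)
  expect_equal(q$concentration, 0.02)  # ratio 1: 0.5 nmol / 25 mg
  expect_equal(q$species, "PC 34:1")

  # zero-intensity species quantifies to zero
  ident0 <- rbind(ident, ident_row("PC 36:2", "PC", 0))
  q0 <- quantify_class(ident0, is_rec, tissue_mass = 25)
  expect_equal(q0$concentration[q0$species == "PC 36:2"], 0)

  # linearity: doubling analyte intensities (standard fixed) doubles
  # concentrations
  ident2 <- ident0
  sel <- !ident2$is_standard
  ident2$corrected[sel] <- 2 * ident2$corrected[sel]
  q2 <- quantify_class(ident2, is_rec, tissue_mass = 25)
  expect_equal(q2$concentration, 2 * q0$concentration)

  # absent or zero standard is a quantification error naming the class
  expect_error(quantify_class(ident_row("PC 34:1", "PC", 500), is_rec, 25),
               "not found.*PC")
  bad <- rbind(ident_row("PC 34:1", "PC", 500),
               ident_row("PC 26:0", "PC", 0, is_standard = TRUE))
  expect_error(quantify_class(bad, is_rec, 25), "non-positive")
})

test_that("the 3.45 factor exactly cancels the ether-PE response deficit", {
  db <- build_species_database(standards = default_internal_standards())
  cc <- cohort_config(strains = "A", replicates_per_group = 2, cv = 0,
                      seed = 2,
                      species_means = data.frame(species = "PE-O 34:2",
                                                 mean_nmol_mg = 1.0 / 25))
  truth <- generate_cohort_truth(cc)
  spectra <- synthesize_spectra(truth,
                                spectrum_noise_model(noise_sd = 0,
                                                     envelope = FALSE), db)
  sp <- spectra[["S01"]][["nl141.total"]]
  sp$peaks <- detect_and_filter(sp, 10)
  ident <- match_to_database(sp, db, 0.3)
  ident <- isotope_correct(ident, enabled = FALSE)
  raw_ratio <- ident$corrected[ident$target == "PE-O 34:2"] /
    ident$corrected[ident$target == "PE 34:0"]
  expect_equal(raw_ratio, 1 / 3.45, tolerance = 1e-12)
  q <- quantify_class(ident, list(class = "PE-O", species = "PE 17:0/17:0",
                                  amount_nmol = 1.0),
                      tissue_mass = 25, lipid_class = "PE-O")
  # recovered concentration equals the spiked-equivalent truth, and the
  # concentration / uncorrected-ratio factor is exactly 3.45
  expect_equal(q$concentration, 1.0 / 25, tolerance = 1e-12)
  expect_equal(q$concentration / (raw_ratio * 1.0 / 25), 3.45,
               tolerance = 1e-12)
  expect_true(q$ether_pe_corrected)
})

test_that("molecular fractions follow the fatty-acyl evidence", {
  db <- build_species_database()
  sum_q <- data.frame(species = "PC 38:6", class = "PC",
                      concentration = 0.8, stringsAsFactors = FALSE)
  fa <- data.frame(
    target = c("PC 16:0/22:6", "PC 16:0/22:6", "PC 18:2/20:4",
               "PC 18:2/20:4"),
    channel = c("fa_16:0", "fa_22:6", "fa_18:2", "fa_20:4"),
    raw = c(1.5, 1.5, 0.5, 0.5), stringsAsFactors = FALSE)
  res <- resolve_molecular_species(sum_q, fa, db)
  expect_equal(sort(res$concentration), c(0.2, 0.6))
  expect_equal(res$fraction[res$species == "PC 16:0/22:6"], 0.75)
  expect_true(all(res$resolved))

  # single detected pair takes the whole sum concentration
  fa1 <- fa[1:2, ]
  res1 <- resolve_molecular_species(sum_q, fa1, db)
  expect_equal(res1$species, "PC 16:0/22:6")
  expect_equal(res1$concentration, 0.8)

  # no evidence: passthrough, flagged unresolved, mass conserved
  res0 <- resolve_molecular_species(sum_q, fa[0, ], db)
  expect_false(res0$resolved)
  expect_equal(res0$level, "sum")
  expect_equal(res0$concentration, 0.8)
})

test_that("isobaric species resolve to their truth ratio at zero noise", {
  db <- build_species_database(standards = default_internal_standards())
  means <- data.frame(species = c("PC 16:0/22:6", "PC 18:2/20:4"),
                      mean_nmol_mg = c(0.8, 0.4))  # 2 : 1, both PC 38:6
  cc <- cohort_config(strains = "A", replicates_per_group = 2, cv = 0,
                      seed = 17, species_means = means)
  truth <- generate_cohort_truth(cc)
  spectra <- synthesize_spectra(truth,
                                spectrum_noise_model(noise_sd = 0,
                                                     envelope = TRUE), db)
  conc <- suppressWarnings(quantify_cohort(spectra, truth$samples, db,
                                           truth$standards))
  s1 <- conc[conc$sample_id == "S01" & conc$concentration > 0, ]
  fr <- s1$concentration / sum(s1$concentration)
  names(fr) <- s1$species
  expect_equal(unname(fr["PC 16:0/22:6"]), 2 / 3, tolerance = 0.01)
  expect_equal(unname(fr["PC 18:2/20:4"]), 1 / 3, tolerance = 0.01)
})

test_that("resolution conserves sum-species totals", {
  db <- build_species_database()
  set.seed(23)
  sums <- c("PC 38:6", "PC 36:4", "PE 38:4", "PS 36:1")
  for (rep_i in 1:10) {
    for (s in sums) {
      cd <- as.integer(strsplit(sub("^\\S+ ", "", s), ":")[[1]])
      cls <- sub(" .*", "", s)
      cands <- db[db$class == cls & db$level == "molecular" &
                    db$carbons == cd[1] & db$double_bonds == cd[2], ]
      # random positive evidence on a random subset of candidate pairs
      n_det <- sample(seq_len(nrow(cands)), 1)
      det <- cands[sample(nrow(cands), n_det), ]
      fa <- do.call(rbind, lapply(seq_len(nrow(det)), function(j) {
        chains <- unique(strsplit(det$chains[j], "/", fixed = TRUE)[[1]])
        data.frame(target = det$name[j], channel = paste0("fa_", chains),
                   raw = runif(length(chains), 0.1, 10),
                   stringsAsFactors = FALSE)
      }))
      sum_q <- data.frame(species = s, class = cls,
                          concentration = runif(1, 0.1, 5),
                          stringsAsFactors = FALSE)
      res <- resolve_molecular_species(sum_q, fa, db)
      expect_equal(sum(res$concentration), sum_q$concentration,
                   tolerance = 1e-9)
      expect_equal(sum(res$fraction), 1, tolerance = 1e-9)
    }
  }
})

test_that("SM detections are named by N-acyl under the d18:1 backbone", {
  expect_equal(assign_sm_backbone("d18:1/18:0")$name, "SM 18:0")
  expect_equal(assign_sm_backbone("d18:1/24:1")$name, "SM 24:1")
  sm <- assign_sm_backbone(fatty_acyl(16, 0))
  expect_equal(sm$name, "SM 16:0")
  expect_equal(sm$backbone, "sphingoid-d18:1")
  expect_error(assign_sm_backbone("d18:0/16:0"), "cannot interpret")
})

test_that("zero-noise end-to-end quantification recovers truth exactly", {
  sim <- zero_noise_sim()
  conc <- zero_noise_conc()
  tr <- sim$truth$truth
  m <- merge(conc, tr, by = c("sample_id", "species"),
             suffixes = c("", ".true"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$concentration, m$concentration.true, tolerance = 1e-9)
  # nothing spurious carries mass
  extra <- conc[!paste(conc$sample_id, conc$species) %in%
                  paste(tr$sample_id, tr$species), ]
  expect_true(all(extra$concentration == 0))
  # class totals equal the generator's class-truth sums
  ct <- class_totals(conc)
  tt <- aggregate(concentration ~ sample_id + class, tr, sum)
  mt <- merge(ct, tt, by = c("sample_id", "class"))
  expect_equal(mt$total, mt$concentration, tolerance = 1e-9)
})
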