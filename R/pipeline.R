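# Run configuration and end-to-end orchestration: simulate a cohort to disk,
# quantify peak lists into the canonical concentration table, and analyze it
# into summary and significance tables.

#' Pipeline parameter defaults
#'
#' The single home of the procedural constants: the s/n inclusion threshold
#' (peaks kept strictly above 10), the ether-PE response correction factor
#' (3.45), the omnibus ANOVA screen alpha (0.05), the protected-LSD alpha
#' (0.01), the m/z matching tolerance (0.3 Th, unit resolution), the
#' smoothing window, and the isotope-correction toggles.
#'
#' @return Named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(
    snr_threshold = 10,
    ether_pe_factor = 3.45,
    omnibus_alpha = 0.05,
    lsd_alpha = 0.01,
    mz_tol = 0.3,
    smoothing_window = 1L,
    isotope_correction = TRUE,
    envelope_model = "binomial",
    pair_evidence = "sum",
    anova_mode = "cells"
  )
}

#' Build a run configuration
#'
#' A flat configuration for the command-style entry points: output paths,
#' the pipeline parameters (see [pipeline_defaults()]), the cohort design
#' and noise model, and the seed. Serialisable to YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param out_dir Output directory for all stages.
#' @param seed Integer seed driving cohort generation and noise.
#' @param params Overrides for [pipeline_defaults()] entries.
#' @param cohort Overrides for [cohort_config()] arguments.
#' @param noise Overrides for [spectrum_noise_model()] arguments.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, params = list(), cohort = list(),
                       noise = list()) {
  p <- utils::modifyList(pipeline_defaults(), params)
  bad <- c("snr_threshold", "omnibus_alpha", "lsd_alpha", "mz_tol")
  if (any(unlist(p[bad]) <= 0)) stop("thresholds must be positive")
  structure(list(out_dir = out_dir, seed = as.integer(seed), params = p,
                 cohort = cohort, noise = noise),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(out_dir = x$out_dir, seed = x$seed,
             params = x$params %||% list(),
             cohort = x$cohort %||% list(), noise = x$noise %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sanitize <- function(x) gsub("[^A-Za-z0-9_.-]", "-", x)

#' Write a simulated cohort to disk
#'
#' One tab-delimited peak list per sample per channel under
#' `peaklists/<sample>/`, a manifest CSV (sample, strain, diet, tissue mass,
#' channel metadata, file path), the ground-truth sidecar CSV, the
#' internal-standard table and the species database.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "peaklists"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (sid in names(sim$spectra)) {
    sdir <- file.path(dir, "peaklists", sid)
    dir.create(sdir, showWarnings = FALSE)
    meta <- sim$truth$samples[sim$truth$samples$sample_id == sid, ]
    for (chan_id in names(sim$spectra[[sid]])) {
      sp <- sim$spectra[[sid]][[chan_id]]
      path <- file.path(sdir, paste0(.sanitize(chan_id), ".tsv"))
      write_peaklist(sp, path)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, strain = meta$strain, diet = meta$diet,
        tissue_mass_mg = meta$tissue_mass_mg, channel = chan_id,
        scan_type = sp$scan_type, polarity = sp$polarity,
        extract = sp$extract,
        path = file.path("peaklists", sid, basename(path)),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$standards, file.path(dir, "standards.csv"),
                   row.names = FALSE)
  write_species_db(sim$db, file.path(dir, "species_db.csv"))
  invisible(manifest)
}

#' Load cohort spectra from a manifest
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `spectra` (per sample, per channel), `samples`,
#'   `standards`, `db`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  samples <- unique(manifest[, c("sample_id", "strain", "diet",
                                 "tissue_mass_mg")])
  rownames(samples) <- NULL
  spectra <- lapply(split(manifest, manifest$sample_id), function(m) {
    chans <- lapply(seq_len(nrow(m)), function(j)
      read_peaklist(file.path(dir, m$path[j]), polarity = m$polarity[j],
                    scan_type = m$scan_type[j], extract = m$extract[j]))
    stats::setNames(chans, m$channel)
  })
  spectra <- spectra[samples$sample_id]
  standards <- utils::read.csv(file.path(dir, "standards.csv"),
                               stringsAsFactors = FALSE)
  db <- read_species_db(file.path(dir, "species_db.csv"))
  list(spectra = spectra, samples = samples, standards = standards, db = db)
}

#' Simulate a synthetic cohort to disk
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly; prints summary counts.
#' @export
cmd_simulate <- function(config) {
  cc <- do.call(cohort_config, utils::modifyList(list(seed = config$seed),
                                                 config$cohort))
  nm <- do.call(spectrum_noise_model, config$noise)
  sim <- simulate_cohort(cc, nm)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- write_cohort(sim, config$out_dir)
  cat("simulated", nrow(sim$truth$samples), "samples (",
      length(unique(sim$truth$samples$strain)), "strains x",
      length(unique(sim$truth$samples$diet)), "diets x",
      cc$replicates_per_group, "replicates),",
      length(unique(manifest$channel)), "channels,",
      nrow(sim$db), "database species\n")
  invisible(config$out_dir)
}

#' Quantify a cohort from peak lists on disk
#'
#' Reads the manifest, peak lists, internal standards and species database
#' from the run directory, executes filtering, matching, isotope correction,
#' internal-standard quantification and molecular-species resolution, and
#' writes the canonical concentration table `concentrations.csv` plus a QC
#' log.
#'
#' @param config A [run_config()].
#' @return The concentration table, invisibly.
#' @export
cmd_quantify <- function(config) {
  cohort <- read_cohort(config$out_dir)
  conc <- quantify_cohort(cohort$spectra, cohort$samples, cohort$db,
                          cohort$standards, params = config$params)
  utils::write.csv(conc, file.path(config$out_dir, "concentrations.csv"),
                   row.names = FALSE)
  qc <- attr(conc, "qc")
  qc_path <- file.path(config$out_dir, "quantify_qc.csv")
  if (!is.null(qc)) utils::write.csv(qc, qc_path, row.names = FALSE)
  cat("quantified", length(unique(conc$sample_id)), "samples,",
      length(unique(conc$species)), "species;",
      if (is.null(qc)) 0 else nrow(qc), "QC flags\n")
  invisible(conc)
}

#' Analyze a quantified cohort
#'
#' Reads `concentrations.csv` from the run directory and writes the derived
#' outputs: the class-by-strain summary grid, the per-sample profile
#' metrics, per-strain diet deltas of the PUFA categories and class totals,
#' the per-species statistics, the significance counts and the ranked
#' p-value diagnostic.
#'
#' @param config A [run_config()].
#' @return The `diet_screen` object, invisibly.
#' @export
cmd_analyze <- function(config) {
  conc <- utils::read.csv(file.path(config$out_dir, "concentrations.csv"),
                          stringsAsFactors = FALSE)
  profiles <- suppressMessages(sample_profiles(conc))
  screen <- diet_screen(conc,
                        omnibus_alpha = config$params$omnibus_alpha,
                        lsd_alpha = config$params$lsd_alpha,
                        anova_mode = config$params$anova_mode)
  deltas <- do.call(rbind, lapply(
    c("pc_pe_ratio", "n6_pl", "n3_pl", "ge1_pufa_pl", "double_pufa_pl"),
    function(m) diet_delta(profiles, m)))
  out <- config$out_dir
  utils::write.csv(table1_summary(conc, screen),
                   file.path(out, "table1_summary.csv"), row.names = FALSE)
  utils::write.csv(profiles, file.path(out, "sample_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(deltas, file.path(out, "diet_deltas.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$anova, file.path(out, "species_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$posthoc, file.path(out, "species_posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$counts, file.path(out, "significance_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$diagnostic, file.path(out, "pvalue_rank.csv"),
                   row.names = FALSE)
  print(screen)
  invisible(screen)
}
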