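# Quantification against class-specific internal standards, the ether-PE
# response factor, and resolution of isobaric phospholipid molecular species
# from negative-mode fatty-acyl evidence.

# positive-mode channels quantify sum groups; the target name an internal
# standard appears under
.sum_target_name <- function(species_name) {
  sp <- parse_shorthand(species_name)
  if (sp$lipid_class %in% c("SM", "CER")) return(sp$name)
  paste0(sp$lipid_class, " ", sum(sp$chains$carbons), ":",
         sum(sp$chains$double_bonds))
}

#' Quantify one lipid class against its internal standard
#'
#' Converts isotope-corrected intensities to absolute concentrations:
#' `conc(i) = corrected(i) / corrected(IS) * amount(IS) / tissue_mass`.
#' Ether-PE concentrations are additionally multiplied by the
#' `ether_pe_factor` (default 3.45), compensating the lower head-group
#' fragment yield of ether-linked PE read against the diacyl-PE standard.
#' The internal-standard row itself is excluded from the result.
#'
#' @param identified Corrected intensities for one sample and channel (from
#'   [isotope_correct()]); must contain the internal standard's target.
#' @param is_record List or one-row data.frame with `class`, `species`,
#'   `amount_nmol`.
#' @param tissue_mass Tissue mass in mg.
#' @param lipid_class Class to quantify (defaults to `is_record$class`).
#' @param ether_pe_factor Response correction factor applied to PE-O.
#' @return data.frame of quantified species: `species` (sum-level target
#'   name), `class`, `concentration` (nmol/mg), `isotope_corrected`,
#'   `ether_pe_corrected`, `source`.
#' @export
quantify_class <- function(identified, is_record, tissue_mass,
                           lipid_class = is_record$class,
                           ether_pe_factor = pipeline_defaults()$ether_pe_factor) {
  if (tissue_mass <= 0) stop("tissue_mass must be positive")
  if (is_record$amount_nmol <= 0) stop("internal-standard amount must be positive")
  is_target <- .sum_target_name(is_record$species)
  is_row <- identified[identified$target == is_target, , drop = FALSE]
  if (nrow(is_row) == 0)
    stop("internal standard ", is_record$species, " (", is_target,
         ") not found among identified intensities for class ", lipid_class)
  if (is_row$corrected[1] <= 0)
    stop("internal standard ", is_target, " has non-positive corrected ",
         "intensity for class ", lipid_class)
  rows <- identified[identified$class == lipid_class &
                       identified$target != is_target, , drop = FALSE]
  factor <- if (lipid_class == "PE-O") ether_pe_factor else 1
  conc <- rows$corrected / is_row$corrected[1] *
    is_record$amount_nmol / tissue_mass * factor
  data.frame(
    species = rows$target, class = lipid_class, concentration = conc,
    isotope_corrected = TRUE, ether_pe_corrected = lipid_class == "PE-O",
    source = "headgroup", stringsAsFactors = FALSE
  )
}

# candidate molecular species of a sum composition, from the database
.sum_candidates <- function(db, lipid_class, sum_carbons, sum_double_bonds) {
  db[db$class == lipid_class & db$level == "molecular" &
       db$carbons == sum_carbons & db$double_bonds == sum_double_bonds &
       !db$is_standard, , drop = FALSE]
}

#' Resolve isobaric phospholipid molecular species
#'
#' Head-group scans quantify PC/PE/PS at sum-composition level; negative-mode
#' fatty-acyl precursor scans determine the chains. For each sum species the
#' candidate diacyl pairs are enumerated from the database, each pair's
#' evidence is the summed fragment intensity of its (distinct) chains at the
#' species' negative-mode precursor m/z, and the fractional intensities of
#' the detected pairs are applied to the sum-level absolute concentration.
#' Sum species with no fatty-acyl evidence are passed through unresolved and
#' flagged, so class totals never lose mass.
#'
#' @param sum_quants Output of [quantify_class()] for PC, PE or PS.
#' @param fa_identified Matched fatty-acyl channel intensities (from
#'   [match_to_database()] on `fa_<C:D>` spectra), with columns `target`,
#'   `channel`, `raw`.
#' @param db A `species_db`.
#' @param combiner `"sum"` (default) or `"min"` of the per-chain fragment
#'   intensities.
#' @return data.frame with columns `species`, `class`, `level`,
#'   `concentration`, `resolved`, `fraction`, `sum_species`.
#' @examples
#' # pairs with evidence 3 and 1 on a 0.8 nmol/mg sum species -> 0.6 and 0.2
#' @export
resolve_molecular_species <- function(sum_quants, fa_identified, db,
                                      combiner = c("sum", "min")) {
  combiner <- match.arg(combiner)
  comb_fun <- if (combiner == "sum") sum else min
  out <- list()
  for (i in seq_len(nrow(sum_quants))) {
    sq <- sum_quants[i, ]
    cd <- as.integer(strsplit(sub("^\\S+ ", "", sq$species), ":")[[1]])
    cands <- .sum_candidates(db, sq$class, cd[1], cd[2])
    evidence <- numeric(nrow(cands))
    if (nrow(fa_identified) > 0 && nrow(cands) > 0) {
      for (j in seq_len(nrow(cands))) {
        chains <- unique(strsplit(cands$chains[j], "/", fixed = TRUE)[[1]])
        per_chain <- vapply(chains, function(ch) {
          hit <- fa_identified$channel == paste0("fa_", ch) &
            fa_identified$target == cands$name[j]
          if (any(hit)) sum(fa_identified$raw[hit]) else 0
        }, numeric(1))
        evidence[j] <- if (all(per_chain > 0)) comb_fun(per_chain) else 0
      }
    }
    if (sum(evidence) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        species = sq$species, class = sq$class, level = "sum",
        concentration = sq$concentration, resolved = FALSE, fraction = 1,
        sum_species = sq$species, stringsAsFactors = FALSE)
      next
    }
    det <- evidence > 0
    frac <- evidence[det] / sum(evidence[det])
    out[[length(out) + 1L]] <- data.frame(
      species = cands$name[det], class = sq$class, level = "molecular",
      concentration = frac * sq$concentration, resolved = TRUE,
      fraction = frac, sum_species = sq$species, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(species = character(), class = character(),
                      level = character(), concentration = numeric(),
                      resolved = logical(), fraction = numeric(),
                      sum_species = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Name an SM detection under the d18:1 backbone assumption
#'
#' The 184.1 precursor scan cannot distinguish isobaric sphingomyelin
#' backbones; detections are assumed to carry the major sphingoid backbone
#' d18:1 and are listed by their N-linked fatty acid.
#'
#' @param detection A backbone/N-acyl string such as `"d18:1/18:0"`, or a
#'   `fatty_acyl` giving the N-linked chain directly.
#' @return A `lipid_species` named `"SM <C>:<D>"` with the d18:1 backbone.
#' @examples
#' assign_sm_backbone("d18:1/18:0")$name  # "SM 18:0"
#' @export
assign_sm_backbone <- function(detection) {
  if (inherits(detection, "fatty_acyl")) {
    return(parse_shorthand(paste0("SM ", detection$carbons, ":",
                                  detection$double_bonds)))
  }
  m <- regexec("^d18:1/(\\d+):(\\d+)$", detection)
  parts <- regmatches(detection, m)[[1]]
  if (length(parts) == 0)
    stop("cannot interpret SM detection '", detection, "'")
  parse_shorthand(paste0("SM ", parts[2], ":", parts[3]))
}

# fatty-acyl channels are evidence lookups at the precursor m/z: a target's
# intensity is the summed filtered-peak intensity within tolerance, and one
# (unresolved) peak may legitimately support several near-isobaric targets
.read_fa_channel <- function(spectrum, db, tol, snr_threshold) {
  pk <- detect_and_filter(spectrum, snr_threshold)
  targets <- .targets_for_channel(db, spectrum$scan_type, spectrum$extract)
  if (nrow(targets) == 0 || nrow(pk) == 0)
    return(data.frame(target = character(), channel = character(),
                      raw = numeric(), stringsAsFactors = FALSE))
  raw <- vapply(targets$mz, function(mz)
    sum(pk$intensity[abs(pk$mz - mz) <= tol]), numeric(1))
  data.frame(target = targets$target, channel = spectrum$scan_type,
             raw = raw, stringsAsFactors = FALSE)[raw > 0, , drop = FALSE]
}

# process one sample's channels: filter, match, isotope-correct positive
# channels; read fatty-acyl evidence channels
.process_sample <- function(channels, db, params) {
  pos <- list(); fa <- list()
  for (chan_id in names(channels)) {
    sp <- channels[[chan_id]]
    if (startsWith(sp$scan_type, "fa_")) {
      fa[[chan_id]] <- .read_fa_channel(sp, db, params$mz_tol,
                                        params$snr_threshold)
      next
    }
    if (params$smoothing_window > 1)
      sp <- smooth_spectrum(sp, params$smoothing_window)
    sp$peaks <- detect_and_filter(sp, params$snr_threshold)
    ident <- match_to_database(sp, db, params$mz_tol)
    pos[[chan_id]] <- isotope_correct(
      ident, model = params$envelope_model, db = db,
      enabled = params$isotope_correction)
  }
  list(positive = do.call(rbind, c(pos, list(NULL))),
       fa = do.call(rbind, c(fa, list(NULL))))
}

#' Quantify every sample of a simulated or loaded cohort
#'
#' Runs the full per-sample chain -- s/n filtering, database matching,
#' isotope correction, internal-standard quantification (with the ether-PE
#' factor), molecular-species resolution -- and assembles the canonical
#' concentration table. A class whose internal standard is missing from a
#' sample is flagged in the `qc` attribute and warned about, not silently
#' dropped.
#'
#' @param spectra Named list (by sample id) of channel lists, as from
#'   [synthesize_spectra()].
#' @param samples Sample table (`sample_id`, `strain`, `diet`,
#'   `tissue_mass_mg`).
#' @param db A `species_db`.
#' @param standards Internal-standard table.
#' @param params Pipeline parameters, see [pipeline_defaults()].
#' @return data.frame: `sample_id`, `strain`, `diet`, `species`, `class`,
#'   `level`, `concentration`, `resolved`; QC notes in `attr(, "qc")`.
#' @export
quantify_cohort <- function(spectra, samples, db, standards,
                            params = pipeline_defaults()) {
  out <- list(); qc <- list()
  classes <- lipid_classes()$class
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    proc <- .process_sample(spectra[[sid]], db, params)
    ident <- proc$positive
    for (cls in classes) {
      if (is.null(ident) || !any(ident$class == cls)) next
      is_record <- standards[standards$class == cls, ]
      if (nrow(is_record) == 0) {
        stop("no internal standard configured for class ", cls)
      }
      quant <- tryCatch(
        quantify_class(ident, as.list(is_record[1, ]),
                       tissue_mass = samples$tissue_mass_mg[i],
                       lipid_class = cls,
                       ether_pe_factor = params$ether_pe_factor),
        error = function(e) e)
      if (inherits(quant, "error")) {
        qc[[length(qc) + 1L]] <- data.frame(
          sample_id = sid, class = cls, note = conditionMessage(quant),
          stringsAsFactors = FALSE)
        warning("sample ", sid, ", class ", cls, ": ",
                conditionMessage(quant))
        next
      }
      if (cls %in% c("PC", "PE", "PS")) {
        res <- resolve_molecular_species(quant, proc$fa, db,
                                         combiner = params$pair_evidence)
        res <- res[, c("species", "class", "level", "concentration",
                       "resolved")]
      } else {
        lev <- if (cls %in% c("SM", "CER")) "molecular" else "sum"
        res <- data.frame(species = quant$species, class = cls, level = lev,
                          concentration = quant$concentration,
                          resolved = cls %in% c("SM", "CER"),
                          stringsAsFactors = FALSE)
      }
      if (nrow(res) == 0) next
      res <- cbind(data.frame(sample_id = sid, strain = samples$strain[i],
                              diet = samples$diet[i],
                              stringsAsFactors = FALSE), res)
      out[[length(out) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, c(out, list(NULL)))
  if (is.null(tab))
    tab <- data.frame(sample_id = character(), strain = character(),
                      diet = character(), species = character(),
                      class = character(), level = character(),
                      concentration = numeric(), resolved = logical(),
                      stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "qc") <- if (length(qc)) do.call(rbind, qc) else NULL
  tab
}
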