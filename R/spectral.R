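# Spectral processing: peak-list containers and I/O, smoothing, s/n
# filtering, database matching, and the two-stage isotope correction
# (M+2/M+4 subtraction from lower-mass neighbours, then normalisation by the
# monoisotopic envelope fraction).

#' Construct a scan spectrum
#'
#' One acquisition channel's centroided peak list together with its polarity,
#' scan type (`"hg184"` head-group precursor scan, `"nl141"` neutral loss,
#' `"cls_<CLASS>"` class scans, `"fa_<C:D>"` fatty-acyl precursor scans) and
#' extract channel (`"total"` or `"hydrolyzed"`).
#'
#' @param peaks data.frame with columns `mz`, `intensity` and optionally
#'   `snr`; rows are sorted ascending by m/z.
#' @param polarity `"+"` or `"-"`.
#' @param scan_type Scan type string.
#' @param extract `"total"` or `"hydrolyzed"`.
#' @return A list of class `scan_spectrum`.
#' @export
scan_spectrum <- function(peaks, polarity = c("+", "-"), scan_type,
                          extract = c("total", "hydrolyzed")) {
  polarity <- match.arg(polarity)
  extract <- match.arg(extract)
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (!"snr" %in% names(peaks)) peaks$snr <- rep(NA_real_, nrow(peaks))
  peaks <- peaks[, c("mz", "intensity", "snr")]
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive")
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  if (is.unsorted(peaks$mz)) peaks <- peaks[order(peaks$mz), ]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, polarity = polarity, scan_type = scan_type,
                 extract = extract),
            class = "scan_spectrum")
}

#' @export
print.scan_spectrum <- function(x, ...) {
  cat("scan_spectrum: ", x$scan_type, " (", x$polarity, ", ", x$extract,
      "), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Write / read a tab-delimited peak list
#'
#' The interchange format is a TSV with a header and columns `mz`,
#' `intensity` and optionally `snr`.
#'
#' @param spectrum A `scan_spectrum`.
#' @param path File path.
#' @param polarity,scan_type,extract Channel metadata to attach on read.
#' @return `read_peaklist` returns a `scan_spectrum`; `write_peaklist` the
#'   path, invisibly.
#' @export
write_peaklist <- function(spectrum, path) {
  utils::write.table(spectrum$peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path, polarity = "+", scan_type = "hg184",
                          extract = "total") {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty peak-list file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("mz", "intensity") %in% header))
    stop("peak-list file ", path, " lacks mz/intensity columns")
  body <- lines[-1]
  peaks <- data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != length(header))
    if (length(bad))
      stop("corrupt peak-list line ", bad[1] + 1L, " in ", path)
    mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                  ncol = length(header), byrow = TRUE,
                  dimnames = list(NULL, header))
    finite_needed <- mat[, c("mz", "intensity"), drop = FALSE]
    if (anyNA(finite_needed))
      stop("corrupt peak-list line ",
           which(rowSums(is.na(finite_needed)) > 0)[1] + 1L, " in ", path)
    peaks <- as.data.frame(mat)
    if (!"snr" %in% names(peaks)) peaks$snr <- NA_real_
  }
  scan_spectrum(peaks, polarity = polarity, scan_type = scan_type,
                extract = extract)
}

#' Moving-average smoothing of a spectrum
#'
#' Averages intensities over a centred window of `window` points with edge
#' truncation (the window shrinks at the spectrum ends); m/z values are
#' unchanged. `window = 1` is the identity.
#'
#' @param spectrum A `scan_spectrum`.
#' @param window Odd integer window width in points.
#' @return The smoothed `scan_spectrum`.
#' @export
smooth_spectrum <- function(spectrum, window = 1L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be an odd integer >= 1")
  if (window == 1L || nrow(spectrum$peaks) == 0) return(spectrum)
  half <- window %/% 2L
  x <- spectrum$peaks$intensity
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  spectrum$peaks$intensity <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  spectrum
}

#' Detect and filter peaks by signal-to-noise ratio
#'
#' Retains peaks whose s/n is strictly greater than the threshold (the
#' inclusion rule "s/n over 10" is read as strict; the boundary is
#' configurable). When the peak list carries no s/n column, s/n is estimated
#' as intensity divided by a robust noise scale, 1.4826 times the median
#' absolute deviation of the intensity distribution (dominated by the
#' non-peak baseline); a zero noise scale leaves all nonzero peaks retained.
#'
#' @param spectrum A `scan_spectrum`.
#' @param snr_threshold Positive s/n threshold (default 10).
#' @return data.frame of retained peaks (`mz`, `intensity`, `snr`).
#' @export
detect_and_filter <- function(spectrum,
                              snr_threshold = pipeline_defaults()$snr_threshold) {
  if (snr_threshold <= 0) stop("snr_threshold must be positive")
  pk <- spectrum$peaks
  if (nrow(pk) == 0) return(pk)
  if (anyNA(pk$snr)) {
    med <- stats::median(pk$intensity)
    scale <- 1.4826 * stats::median(abs(pk$intensity - med))
    pk$snr <- if (scale > 0) pk$intensity / scale else
      ifelse(pk$intensity > 0, Inf, 0)
  }
  out <- pk[pk$snr > snr_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# target table for any channel, including fatty-acyl precursor channels
.targets_for_channel <- function(db, scan_type, extract) {
  if (startsWith(scan_type, "fa_")) {
    chain <- sub("^fa_", "", scan_type)
    mol <- db[db$level == "molecular" & db$class %in% c("PC", "PE", "PS"), ,
              drop = FALSE]
    sel <- vapply(strsplit(mol$chains, "/", fixed = TRUE),
                  function(x) chain %in% x, logical(1))
    mol <- mol[sel, , drop = FALSE]
    return(data.frame(target = mol$name, class = mol$class,
                      carbons = mol$n_carbon_atoms,
                      sum_carbons = mol$carbons,
                      sum_double_bonds = mol$double_bonds,
                      mz = mol$mz_neg, is_standard = mol$is_standard,
                      stringsAsFactors = FALSE))
  }
  .channel_targets(db, scan_type, extract)
}

#' Match filtered peaks to database targets
#'
#' Each peak is assigned to the nearest database target within `tol`;
#' unassigned peaks are dropped. A peak maps to at most one target and a
#' target keeps only its nearest peak. Two targets exactly equidistant from
#' a peak resolve to the lower-m/z target (reported via `message()`). In
#' positive-mode channels a peak whose tolerance window contains both an
#' ether-linked and a (non-standard) odd-chain interpretation is assigned to
#' the ether species.
#'
#' @param spectrum A `scan_spectrum` whose peaks have passed filtering, or a
#'   peak data.frame plus channel metadata via `scan_type`/`extract`.
#' @param db A `species_db`.
#' @param tol m/z matching tolerance in Th (default 0.3, unit-resolution).
#' @return data.frame of identified intensities: `target`, `class`,
#'   `channel`, `extract`, `mz`, `target_mz`, `raw`, plus carbon counts used
#'   by isotope correction.
#' @export
match_to_database <- function(spectrum, db,
                              tol = pipeline_defaults()$mz_tol) {
  stopifnot(tol > 0)
  pk <- if (inherits(spectrum, "scan_spectrum")) spectrum$peaks else spectrum
  targets <- .targets_for_channel(db, spectrum$scan_type, spectrum$extract)
  empty <- data.frame(target = character(), class = character(),
                      channel = character(), extract = character(),
                      mz = numeric(), target_mz = numeric(), raw = numeric(),
                      carbons = integer(), sum_carbons = integer(),
                      sum_double_bonds = integer(), is_standard = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(pk) == 0 || nrow(targets) == 0) return(empty)
  assign_idx <- integer(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    d <- abs(targets$mz - pk$mz[i])
    cand <- which(d <= tol)
    if (length(cand) == 0) { assign_idx[i] <- NA_integer_; next }
    ether <- targets$class[cand] %in% c("PC-O", "PE-O")
    odd <- targets$sum_carbons[cand] %% 2 == 1 &
      !targets$is_standard[cand] & !ether
    if (any(ether) && any(odd)) {
      keep <- cand[ether]
      message("ether/odd-chain ambiguity at m/z ", format(pk$mz[i]),
              ": assigned ", targets$target[keep[which.min(d[keep])]])
      cand <- keep
    }
    best <- cand[d[cand] <= min(d[cand]) + 1e-9]
    if (length(best) > 1) {
      best <- best[which.min(targets$mz[best])]
      message("tie at m/z ", format(pk$mz[i]), " broken toward lower-m/z ",
              "target ", targets$target[best])
    } else best <- best[1]
    assign_idx[i] <- best
  }
  ok <- !is.na(assign_idx)
  if (!any(ok)) return(empty)
  pk <- pk[ok, , drop = FALSE]; assign_idx <- assign_idx[ok]
  # one peak per target: keep the nearest
  err <- abs(pk$mz - targets$mz[assign_idx])
  keep <- !logical(nrow(pk))
  for (tgt in unique(assign_idx[duplicated(assign_idx)])) {
    rows <- which(assign_idx == tgt)
    keep[rows[-which.min(err[rows])]] <- FALSE
  }
  pk <- pk[keep, , drop = FALSE]; assign_idx <- assign_idx[keep]
  data.frame(
    target = targets$target[assign_idx], class = targets$class[assign_idx],
    channel = spectrum$scan_type, extract = spectrum$extract,
    mz = pk$mz, target_mz = targets$mz[assign_idx], raw = pk$intensity,
    carbons = targets$carbons[assign_idx],
    sum_carbons = targets$sum_carbons[assign_idx],
    sum_double_bonds = targets$sum_double_bonds[assign_idx],
    is_standard = targets$is_standard[assign_idx],
    stringsAsFactors = FALSE
  )
}

.envelope_coeffs <- function(identified, model, p13c, db) {
  if (model == "binomial") {
    env <- lapply(identified$carbons, function(nc)
      stats::dbinom(0:4, size = nc, prob = p13c))
  } else {
    if (is.null(db)) stop("convolution model needs the species database")
    frm <- stats::setNames(db$formula, db$name)
    # positive channels quantify sum groups; use any member's formula (all
    # members of a sum group share the elemental composition)
    look <- function(tgt, cls) {
      hit <- db[db$class == cls &
                  paste(db$class, paste0(db$carbons, ":", db$double_bonds)) == tgt |
                  db$name == tgt, , drop = FALSE]
      if (nrow(hit) == 0) stop("no composition available for ", tgt)
      hit$formula[1]
    }
    env <- lapply(seq_len(nrow(identified)), function(i)
      isotope_envelope(.parse_formula(
        look(identified$target[i], identified$class[i])), 4L, "convolution"))
  }
  env
}

#' Two-stage isotope correction of identified intensities
#'
#' Stage 1 removes the isotope contribution of lower-mass species: within
#' each channel and class, proceeding in ascending m/z, the M+2 (and M+4)
#' isotopologue intensity of the species with one (two) more double bonds --
#' which overlaps the monoisotopic peak at unit resolution -- is subtracted:
#' `corrected(i) = raw(i) - a2(j) corrected(j) - a4(k) corrected(k)`, with
#' `a2 = f2/f0`, `a4 = f4/f0` from the neighbour's envelope. Negative results
#' are clamped to zero with a warning. Stage 2 corrects for the isotope
#' distribution itself, dividing by the monoisotopic fraction `f0` so that
#' intensities represent total species abundance. Envelope coefficients come
#' from the carbon binomial by default or the full multi-element convolution
#' (`model = "convolution"`, which requires `db`).
#'
#' @param identified Output of [match_to_database()].
#' @param model `"binomial"` or `"convolution"`.
#' @param p13c 13C abundance for the binomial model.
#' @param db Species database (required for the convolution model).
#' @param enabled Set `FALSE` to make the correction the identity (for data
#'   synthesized without envelopes).
#' @return `identified` with a `corrected` column appended.
#' @export
isotope_correct <- function(identified, model = c("binomial", "convolution"),
                            p13c = 0.0107, db = NULL, enabled = TRUE,
                            tol = pipeline_defaults()$mz_tol) {
  model <- match.arg(model)
  identified$corrected <- identified$raw
  if (!enabled || nrow(identified) == 0) return(identified)
  env <- .envelope_coeffs(identified, model, p13c, db)
  f0 <- vapply(env, `[`, numeric(1), 1L)
  a2 <- vapply(env, function(e) e[3] / e[1], numeric(1))
  a4 <- vapply(env, function(e) e[5] / e[1], numeric(1))
  grp <- paste(identified$channel, identified$extract)
  clamped <- character(0)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    rows <- rows[order(identified$target_mz[rows])]
    # floating-point residue floor: subtraction of a neighbour's full
    # contribution should give exactly zero, not +/-1e-12 of the signal
    floor_at <- 1e-9 * max(identified$raw[rows], 1)
    # where each species' M+2 / M+4 isotopologue falls, and which target in
    # the channel that position matches (at unit resolution the dominant
    # landing site is the species with one fewer double bond, 2.0157 Th up;
    # near-isobars of other classes can capture it too)
    contrib <- matrix(NA_integer_, length(rows), 2)
    for (jj in seq_along(rows)) {
      for (step in c(1L, 2L)) {
        pos <- identified$target_mz[rows[jj]] + 2 * step * .C13_C12_DIFF
        d <- abs(identified$target_mz[rows] - pos)
        hit <- which.min(d)
        if (d[hit] <= tol && hit != jj) contrib[jj, step] <- hit
      }
    }
    for (ii in seq_along(rows)) {
      corr <- identified$raw[rows[ii]]
      for (step in c(1L, 2L)) {
        src <- which(contrib[, step] == ii)
        for (jj in src) {
          coef <- if (step == 1L) a2[rows[jj]] else a4[rows[jj]]
          corr <- corr - coef * identified$corrected[rows[jj]]
        }
      }
      if (corr < -floor_at) clamped <- c(clamped, identified$target[rows[ii]])
      if (corr < floor_at) corr <- 0
      identified$corrected[rows[ii]] <- corr
    }
  }
  if (length(clamped))
    warning("negative corrected intensities clamped to zero for: ",
            paste(unique(clamped), collapse = ", "))
  identified$corrected <- identified$corrected / f0
  identified
}
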