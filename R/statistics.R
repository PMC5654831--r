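# Significance pipeline: log transform, per-species one-way ANOVA across
# strain-by-diet cells, the rank/normal-probability diagnostic, protected
# Fisher's LSD within strain, and directional change counts.

#' Log-transform a species-by-sample concentration matrix
#'
#' Natural logs are taken to bring the (positively skewed) concentration
#' distributions close to normal before ANOVA. Zeros are replaced by half
#' the species' minimum positive value first (each replacement is reported
#' via `message()`); species that are zero in every sample cannot be
#' transformed and are dropped (also reported).
#'
#' @param mat Numeric matrix, species in rows, samples in columns; values
#'   must be >= 0.
#' @return List with `log_mat` (transformed matrix), `replaced` (named count
#'   of zero replacements per species) and `dropped` (all-zero species
#'   names).
#' @export
log_transform <- function(mat) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0)) stop("concentrations must be >= 0")
  all_zero <- rownames(mat)[rowSums(mat > 0) == 0]
  if (length(all_zero))
    message("dropping all-zero species: ", paste(all_zero, collapse = ", "))
  mat <- mat[!rownames(mat) %in% all_zero, , drop = FALSE]
  replaced <- integer(0)
  for (i in seq_len(nrow(mat))) {
    z <- mat[i, ] == 0
    if (any(z)) {
      mat[i, z] <- min(mat[i, !z]) / 2
      replaced[rownames(mat)[i]] <- sum(z)
      message("replaced ", sum(z), " zero(s) in ", rownames(mat)[i],
              " by half the minimum positive value")
    }
  }
  list(log_mat = log(mat), replaced = replaced, dropped = all_zero)
}

#' One-way omnibus ANOVA across design cells
#'
#' Standard one-way ANOVA of one species' (transformed) values across all
#' strain-by-diet cells, via [stats::aov()]. With zero within-cell variance
#' everywhere the F statistic is undefined; by convention p is 0 when cell
#' means differ and 1 when they are identical (reported via `message()`).
#'
#' @param values Numeric vector of per-sample values.
#' @param cell Factor assigning each sample to a design cell.
#' @return List: `F`, `p`, `df_between`, `df_within`, `mse` (pooled
#'   within-cell variance).
#' @export
omnibus_anova <- function(values, cell) {
  cell <- droplevels(as.factor(cell))
  if (nlevels(cell) < 2) stop("need at least two design cells")
  fit <- stats::aov(values ~ cell)
  sm <- summary(fit)[[1]]
  mse <- sm["Residuals", "Mean Sq"]
  f <- sm[1, "F value"]; p <- sm[1, "Pr(>F)"]
  # an MSE at floating-point-residue scale is a zero within-cell variance
  mse_floor <- 1e-12 * max(sum((values - mean(values))^2),
                           max(abs(values))^2, .Machine$double.xmin)
  if (!is.finite(mse) || mse <= mse_floor) {
    means <- tapply(values, cell, mean)
    identical_means <- max(means) - min(means) < .Machine$double.eps^0.5 *
      max(1, max(abs(means)))
    p <- if (identical_means) 1 else 0
    f <- if (identical_means) 0 else Inf
    mse <- 0
    message("zero within-cell variance: omnibus p set to ", p,
            " by convention")
  }
  list(F = unname(f), p = unname(p),
       df_between = sm[1, "Df"], df_within = sm["Residuals", "Df"],
       mse = unname(mse))
}

#' Ranked p-value diagnostic
#'
#' The screening diagnostic: ANOVA p values sorted ascending with their
#' ranks and the expected uniform quantiles `rank / (m + 1)` for a
#' normal-probability-style plot. Strong departure from the diagonal at low
#' ranks indicates an excess of small p values. Purely diagnostic: the
#' operative screen is the omnibus alpha, not this plot.
#'
#' @param p Numeric vector of ANOVA p values (>= 2).
#' @return data.frame: `species` (names of `p`, if any), `p`, `rank`,
#'   `expected_uniform`.
#' @export
rank_pvalue_diagnostic <- function(p) {
  if (length(p) < 2) stop("need at least two p values")
  o <- order(p)
  data.frame(
    species = if (is.null(names(p))) NA_character_ else names(p)[o],
    p = p[o], rank = seq_along(p),
    expected_uniform = seq_along(p) / (length(p) + 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Protected Fisher's LSD post-hoc tests
#'
#' Post-hoc testing is performed only when the omnibus ANOVA p value clears
#' the screen (`p < omnibus_alpha`); otherwise no records are produced (the
#' "protection"). For each strain with both diet groups, the LSD statistic
#' uses the pooled ANOVA error:
#' `t = (mean_HFD - mean_CHOW) / sqrt(MSE (1/n1 + 1/n2))` with the omnibus
#' within-cell degrees of freedom and a two-sided p value. A comparison is
#' significant when `p < lsd_alpha`; its direction comes from the sign of
#' the raw (untransformed) mean difference.
#'
#' @param anova_res Result of [omnibus_anova()] for the species.
#' @param values Transformed per-sample values.
#' @param raw_values Raw per-sample values (for the direction).
#' @param strain,diet Per-sample design labels.
#' @param diets Control and intervention diet labels.
#' @param omnibus_alpha Screen threshold (default 0.05).
#' @param lsd_alpha Post-hoc threshold (default 0.01).
#' @return data.frame with one row per tested strain: `strain`, `t`, `p`,
#'   `direction` (`"up"`, `"down"`, `"none"`), `significant`.
#' @export
protected_lsd <- function(anova_res, values, raw_values, strain, diet,
                          diets = c("CHOW", "HFD"),
                          omnibus_alpha = pipeline_defaults()$omnibus_alpha,
                          lsd_alpha = pipeline_defaults()$lsd_alpha) {
  empty <- data.frame(strain = character(), t = numeric(), p = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (anova_res$p >= omnibus_alpha) return(empty)
  rows <- lapply(unique(strain), function(st) {
    i0 <- strain == st & diet == diets[1]
    i1 <- strain == st & diet == diets[2]
    if (!any(i0) || !any(i1)) {
      message("strain ", st, " lacks a diet group; skipped in post-hoc")
      return(NULL)
    }
    diff_t <- mean(values[i1]) - mean(values[i0])
    se <- sqrt(anova_res$mse * (1 / sum(i1) + 1 / sum(i0)))
    t <- if (se > 0) diff_t / se else if (diff_t == 0) 0 else Inf * sign(diff_t)
    p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df = anova_res$df_within)
    else 0
    if (se == 0 && diff_t == 0) p <- 1
    sig <- p < lsd_alpha
    raw_diff <- mean(raw_values[i1]) - mean(raw_values[i0])
    dir <- if (!sig || raw_diff == 0) "none" else
      if (raw_diff > 0) "up" else "down"
    data.frame(strain = st, t = t, p = p, direction = dir,
               significant = sig && dir != "none", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) empty else out
}

#' Count significant directional changes per class and strain
#'
#' The machine form of the summary table's arrows: per class and strain, the
#' number of species significantly decreased or increased with the
#' intervention diet.
#'
#' @param posthoc data.frame of post-hoc records with columns `species`,
#'   `class`, `strain`, `direction`, `significant`.
#' @param classes,strains Levels of the output grid.
#' @return data.frame: `class`, `strain`, `n_down`, `n_up`.
#' @export
count_directional_changes <- function(posthoc,
                                      classes = .CLASS_NAMES,
                                      strains = unique(posthoc$strain)) {
  grid <- expand.grid(class = classes, strain = strains,
                      stringsAsFactors = FALSE)
  sig <- posthoc[posthoc$significant, , drop = FALSE]
  grid$n_down <- mapply(function(cl, st)
    sum(sig$class == cl & sig$strain == st & sig$direction == "down"),
    grid$class, grid$strain)
  grid$n_up <- mapply(function(cl, st)
    sum(sig$class == cl & sig$strain == st & sig$direction == "up"),
    grid$class, grid$strain)
  grid
}

#' Screen a concentration table for diet effects
#'
#' The full significance pipeline over every species of a cohort: natural-log
#' transform (with half-minimum zero substitution), per-species one-way
#' ANOVA -- by default a single omnibus ANOVA across all strain-by-diet
#' cells, whose pooled error the post-hoc tests reuse; `anova_mode =
#' "per_strain"` instead runs a two-group ANOVA within each strain --
#' followed by protected Fisher's LSD diet comparisons within each strain
#' and directional change counts per class.
#'
#' @param conc_table Canonical concentration table (see
#'   [quantify_cohort()]).
#' @param omnibus_alpha Omnibus screen threshold.
#' @param lsd_alpha Post-hoc significance threshold.
#' @param anova_mode `"cells"` (one ANOVA over all strain-by-diet cells) or
#'   `"per_strain"` (two-group ANOVA within each strain).
#' @param diets Control and intervention diet labels.
#' @return An object of class `diet_screen`: list with `anova` (per-species
#'   F, p, MSE), `posthoc` (per species and strain LSD records), `counts`
#'   (class-by-strain directional counts), `diagnostic` (ranked p table)
#'   and the thresholds used.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(cohort_config(seed = 7))
#' conc <- quantify_cohort(sim$spectra, sim$truth$samples, sim$db,
#'                         sim$truth$standards)
#' scr <- diet_screen(conc)
#' summary(scr)
#' }
#' @export
diet_screen <- function(conc_table,
                        omnibus_alpha = pipeline_defaults()$omnibus_alpha,
                        lsd_alpha = pipeline_defaults()$lsd_alpha,
                        anova_mode = c("cells", "per_strain"),
                        diets = c("CHOW", "HFD")) {
  anova_mode <- match.arg(anova_mode)
  meta <- unique(conc_table[, c("sample_id", "strain", "diet")])
  mat <- stats::xtabs(concentration ~ species + sample_id, conc_table)
  mat <- matrix(mat, nrow = nrow(mat), dimnames = dimnames(mat))
  mat <- mat[, meta$sample_id, drop = FALSE]
  lt <- suppressMessages(log_transform(mat))
  lmat <- lt$log_mat
  rawmat <- mat[rownames(lmat), , drop = FALSE]
  sp_class <- conc_table$class[match(rownames(lmat), conc_table$species)]
  cell <- factor(paste(meta$strain, meta$diet))
  anova_rows <- list(); ph_rows <- list()
  for (i in seq_len(nrow(lmat))) {
    sp <- rownames(lmat)[i]
    if (anova_mode == "cells") {
      a <- suppressMessages(omnibus_anova(lmat[i, ], cell))
      ph <- protected_lsd(a, lmat[i, ], rawmat[i, ], meta$strain, meta$diet,
                          diets, omnibus_alpha, lsd_alpha)
      anova_rows[[i]] <- data.frame(species = sp, class = sp_class[i],
                                    F = a$F, p = a$p, df_between = a$df_between,
                                    df_within = a$df_within, mse = a$mse,
                                    stringsAsFactors = FALSE)
    } else {
      per <- lapply(unique(meta$strain), function(st) {
        sel <- meta$strain == st
        a <- suppressMessages(omnibus_anova(lmat[i, sel],
                                            factor(meta$diet[sel])))
        ph <- protected_lsd(a, lmat[i, sel], rawmat[i, sel],
                            meta$strain[sel], meta$diet[sel], diets,
                            omnibus_alpha, lsd_alpha)
        list(a = a, ph = ph, strain = st)
      })
      # report the smallest-p strain as the species' screening record
      ps <- vapply(per, function(x) x$a$p, numeric(1))
      a <- per[[which.min(ps)]]$a
      ph <- do.call(rbind, lapply(per, `[[`, "ph"))
      anova_rows[[i]] <- data.frame(species = sp, class = sp_class[i],
                                    F = a$F, p = a$p, df_between = a$df_between,
                                    df_within = a$df_within, mse = a$mse,
                                    stringsAsFactors = FALSE)
    }
    if (nrow(ph)) {
      ph$species <- sp; ph$class <- sp_class[i]
      ph_rows[[length(ph_rows) + 1L]] <- ph
    }
  }
  anova_tab <- do.call(rbind, anova_rows)
  posthoc <- do.call(rbind, c(ph_rows, list(NULL)))
  if (is.null(posthoc))
    posthoc <- data.frame(strain = character(), t = numeric(), p = numeric(),
                          direction = character(), significant = logical(),
                          species = character(), class = character(),
                          stringsAsFactors = FALSE)
  counts <- count_directional_changes(posthoc, strains = unique(meta$strain))
  pvec <- stats::setNames(anova_tab$p, anova_tab$species)
  structure(list(anova = anova_tab, posthoc = posthoc, counts = counts,
                 diagnostic = rank_pvalue_diagnostic(pvec),
                 omnibus_alpha = omnibus_alpha, lsd_alpha = lsd_alpha,
                 anova_mode = anova_mode, diets = diets),
            class = "diet_screen")
}

#' @export
print.diet_screen <- function(x, ...) {
  cat("diet_screen: ", nrow(x$anova), " species, omnibus alpha ",
      x$omnibus_alpha, ", LSD alpha ", x$lsd_alpha, " (", x$anova_mode,
      " ANOVA)\n", sep = "")
  cat("  species passing omnibus screen: ",
      sum(x$anova$p < x$omnibus_alpha), "\n", sep = "")
  cat("  significant post-hoc calls: ", sum(x$posthoc$significant),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.diet_screen <- function(object, ...) {
  cnt <- object$counts
  cnt <- cnt[cnt$n_down + cnt$n_up > 0, , drop = FALSE]
  cat("Significant diet-induced changes (", object$diets[2], " vs ",
      object$diets[1], ", LSD p < ", object$lsd_alpha, "):\n", sep = "")
  if (nrow(cnt) == 0) cat("  none\n") else
    print(cnt, row.names = FALSE)
  invisible(object$counts)
}
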