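# Derived lipidome metrics: per-sample class totals, the PC/PE ratio, PUFA
# category sums (n-6, n-3, >=1-PUFA, double-PUFA phospholipids), diet-induced
# deltas, species counts, and the class-by-strain summary grid.

.PL_CLASSES <- c("PC", "PC-O", "PE", "PE-O", "PS")

#' Per-sample, per-class concentration totals
#'
#' Sums member species concentrations within each class, using molecular
#' level where resolved and sum level otherwise. A species represented at
#' both levels in the same sample would be counted twice and raises an
#' error.
#'
#' @param conc_table Canonical concentration table (see
#'   [quantify_cohort()]).
#' @return data.frame: `sample_id`, `class`, `total` (nmol/mg).
#' @export
class_totals <- function(conc_table) {
  if (nrow(conc_table) == 0)
    return(data.frame(sample_id = character(), class = character(),
                      total = numeric(), stringsAsFactors = FALSE))
  sum_name <- ifelse(conc_table$level == "molecular" &
                       conc_table$class %in% c("PC", "PE", "PS"),
                     vapply(conc_table$species, .sum_target_name,
                            character(1), USE.NAMES = FALSE),
                     conc_table$species)
  key <- paste(conc_table$sample_id, sum_name)
  both <- tapply(conc_table$level, key,
                 function(l) length(unique(l)) > 1)
  if (any(both))
    stop("species counted at both sum and molecular level: ",
         paste(utils::head(names(both)[both], 3), collapse = ", "))
  agg <- stats::aggregate(concentration ~ sample_id + class, conc_table, sum)
  names(agg)[3] <- "total"
  agg[order(agg$sample_id, match(agg$class, .CLASS_NAMES)), ]
}

#' PC/PE ratio
#'
#' Ratio of phosphatidylcholine to phosphatidylethanolamine totals, the
#' membrane-composition index linked to insulin action. By default the
#' diacyl totals are used and the ether subclasses are excluded
#' (configurable).
#'
#' @param pc_total,pe_total Class totals in nmol/mg (vectors allowed).
#' @return The ratio; an error when any PE total is zero while the paired PC
#'   total is nonzero (the ratio is undefined), and 0 where both are 0 or PC
#'   alone is 0.
#' @examples
#' pc_pe_ratio(11.27, 3.15)  # 3.578 for the reference CHOW totals
#' @export
pc_pe_ratio <- function(pc_total, pe_total) {
  if (any(pe_total == 0 & pc_total != 0))
    stop("PC/PE ratio undefined: PE total is zero")
  ifelse(pc_total == 0, 0, pc_total / pe_total)
}

#' Per-sample PUFA category sums for phospholipids
#'
#' From the molecular-species diacyl phospholipids (PC, PE, PS) of each
#' sample: the summed concentration of species containing an n-6 chain, an
#' n-3 chain, at least one PUFA chain, and two PUFA chains (a PUFA is a
#' chain with >= 2 double bonds). A species with one n-6 and one n-3 chain
#' counts in both family sums. Unresolved sum-level phospholipids cannot be
#' classified and are excluded from the categories (reported via
#' `message()`), but still count toward the total phospholipid pool used
#' for `double_pufa_share`.
#'
#' @param conc_table Canonical concentration table.
#' @param omega_table Omega-family lookup, see [default_omega_table()].
#' @return data.frame: `sample_id`, `n6_pl`, `n3_pl`, `ge1_pufa_pl`,
#'   `double_pufa_pl`, `total_pl`, `double_pufa_share`.
#' @export
pufa_category_sums <- function(conc_table, omega_table = default_omega_table()) {
  pl <- conc_table[conc_table$class %in% .PL_CLASSES, , drop = FALSE]
  mol <- pl[pl$level == "molecular" & pl$class %in% c("PC", "PE", "PS"), ,
            drop = FALSE]
  n_unres <- sum(!(pl$level == "molecular" & pl$class %in% c("PC", "PE", "PS")) &
                   !pl$class %in% c("PC-O", "PE-O"))
  if (n_unres > 0)
    message(n_unres, " unresolved sum-level phospholipid rows excluded ",
            "from PUFA categories")
  species <- unique(mol$species)
  flags <- do.call(rbind, lapply(species, function(nm) {
    sp <- parse_shorthand(nm)
    cl <- lapply(seq_len(nrow(sp$chains)), function(k)
      classify_acyl(fatty_acyl(sp$chains$carbons[k],
                               sp$chains$double_bonds[k]), omega_table))
    fams <- vapply(cl, `[[`, character(1), "omega_family")
    pufa <- vapply(cl, `[[`, logical(1), "is_pufa")
    data.frame(species = nm,
               n6 = any(fams == "n-6" & pufa), n3 = any(fams == "n-3" & pufa),
               ge1 = sum(pufa) >= 1, dbl = sum(pufa) == 2,
               stringsAsFactors = FALSE)
  }))
  samples <- unique(conc_table$sample_id)
  out <- do.call(rbind, lapply(samples, function(sid) {
    m <- mol[mol$sample_id == sid, ]
    f <- flags[match(m$species, flags$species), , drop = FALSE]
    tot_pl <- sum(pl$concentration[pl$sample_id == sid])
    dbl <- sum(m$concentration[f$dbl])
    data.frame(
      sample_id = sid,
      n6_pl = sum(m$concentration[f$n6]), n3_pl = sum(m$concentration[f$n3]),
      ge1_pufa_pl = sum(m$concentration[f$ge1]), double_pufa_pl = dbl,
      total_pl = tot_pl,
      double_pufa_share = if (tot_pl > 0) dbl / tot_pl else 0,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample profile of derived metrics
#'
#' Class totals (wide), the PC/PE ratio (diacyl by default) and the PUFA
#' category sums, one row per sample.
#'
#' @param conc_table Canonical concentration table.
#' @param omega_table Omega-family lookup.
#' @param include_ether_in_ratio Include PC-O / PE-O totals in the PC/PE
#'   ratio numerator and denominator.
#' @return data.frame keyed by `sample_id` with `strain`, `diet`, one column
#'   per class total, `pc_pe_ratio` and the PUFA category columns.
#' @export
sample_profiles <- function(conc_table, omega_table = default_omega_table(),
                            include_ether_in_ratio = FALSE) {
  tot <- class_totals(conc_table)
  wide <- stats::reshape(tot, idvar = "sample_id", timevar = "class",
                         direction = "wide")
  names(wide) <- sub("^total\\.", "", names(wide))
  for (cls in .CLASS_NAMES) if (!cls %in% names(wide)) wide[[cls]] <- 0
  wide[is.na(wide)] <- 0
  meta <- unique(conc_table[, c("sample_id", "strain", "diet")])
  out <- merge(meta, wide, by = "sample_id")
  pc <- out$PC + if (include_ether_in_ratio) out$`PC-O` else 0
  pe <- out$PE + if (include_ether_in_ratio) out$`PE-O` else 0
  out$pc_pe_ratio <- pc_pe_ratio(pc, pe)
  cats <- pufa_category_sums(conc_table, omega_table)
  out <- merge(out, cats, by = "sample_id")
  out[order(out$sample_id), ]
}

#' Diet-induced change in a metric, per strain
#'
#' Arithmetic mean difference on raw (untransformed) values:
#' mean(HFD) - mean(CHOW) per strain; negative values indicate a
#' diet-induced decrease.
#'
#' @param data data.frame with columns `strain`, `diet` and the metric.
#' @param metric Name of the metric column.
#' @param diets Length-2 character: control and intervention diet labels.
#' @return data.frame: `strain`, `metric`, `delta`.
#' @export
diet_delta <- function(data, metric, diets = c("CHOW", "HFD")) {
  stopifnot(metric %in% names(data))
  out <- do.call(rbind, lapply(unique(data$strain), function(st) {
    x0 <- data[[metric]][data$strain == st & data$diet == diets[1]]
    x1 <- data[[metric]][data$strain == st & data$diet == diets[2]]
    if (length(x0) == 0 || length(x1) == 0)
      stop("strain ", st, " is missing diet group ",
           diets[c(length(x0) == 0, length(x1) == 0)][1])
    data.frame(strain = st, metric = metric, delta = mean(x1) - mean(x0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detected species counts per class
#'
#' A species is detected when its concentration is nonzero in at least one
#' sample.
#'
#' @param conc_table Canonical concentration table.
#' @return data.frame: `class`, `n_species`.
#' @export
species_count_summary <- function(conc_table) {
  det <- conc_table[conc_table$concentration > 0, , drop = FALSE]
  n <- vapply(.CLASS_NAMES, function(cls)
    length(unique(det$species[det$class == cls])), integer(1))
  data.frame(class = .CLASS_NAMES, n_species = unname(n),
             stringsAsFactors = FALSE)
}

#' Class-by-strain summary grid
#'
#' The machine form of the study's class summary table: per class and strain
#' the CHOW and HFD mean +/- SEM of class totals (nmol/mg), the number of
#' detected species in the class, and -- when a [diet_screen()] result is
#' supplied -- the number of species significantly decreased or increased
#' with the intervention diet.
#'
#' @param conc_table Canonical concentration table.
#' @param screen Optional `diet_screen` object.
#' @param diets Control and intervention diet labels.
#' @return A long-format data.frame, one row per class and strain.
#' @export
table1_summary <- function(conc_table, screen = NULL,
                           diets = c("CHOW", "HFD")) {
  tot <- class_totals(conc_table)
  meta <- unique(conc_table[, c("sample_id", "strain", "diet")])
  tot <- merge(tot, meta, by = "sample_id")
  counts <- species_count_summary(conc_table)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  grid <- expand.grid(class = .CLASS_NAMES, strain = unique(meta$strain),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- tot$class == grid$class[i] & tot$strain == grid$strain[i]
    x0 <- tot$total[sel & tot$diet == diets[1]]
    x1 <- tot$total[sel & tot$diet == diets[2]]
    sig <- c(down = 0L, up = 0L)
    if (!is.null(screen)) {
      cnt <- screen$counts
      hit <- cnt$class == grid$class[i] & cnt$strain == grid$strain[i]
      if (any(hit)) sig <- c(down = cnt$n_down[hit][1], up = cnt$n_up[hit][1])
    }
    data.frame(
      class = grid$class[i], strain = grid$strain[i],
      n_species = counts$n_species[counts$class == grid$class[i]],
      chow_mean = mean(x0), chow_sem = sem(x0),
      hfd_mean = mean(x1), hfd_sem = sem(x1),
      n_down = sig[["down"]], n_up = sig[["up"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
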