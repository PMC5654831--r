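# Target species database: enumerate species over a finite chain space,
# attach elemental compositions, monoisotopic masses and per-channel target
# m/z values, and support CSV round-trips.

#' Default chain space for the species database
#'
#' Bounds the enumerated database: a common-acyl list for diacyl
#' phospholipids, even-carbon sum-composition ranges for TAG/DAG and the
#' ether classes, and N-acyl lists for the sphingolipids. Odd-chain species
#' enter the database only as internal standards or through the explicit
#' ether/odd-chain assignment rule.
#'
#' @return A list with components `pl_acyls`, `ether`, `tag`, `dag`,
#'   `ce_acyls`, `n_acyls`.
#' @export
default_chain_space <- function() {
  list(
    pl_acyls = c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "18:3",
                 "20:3", "20:4", "20:5", "22:4", "22:5", "22:6"),
    ether    = list(carbons = seq(30L, 40L, 2L), double_bonds = 0:6),
    tag      = list(carbons = seq(48L, 56L, 2L), double_bonds = 0:7),
    dag      = list(carbons = seq(30L, 40L, 2L), double_bonds = 0:6),
    ce_acyls = c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "20:4",
                 "22:6"),
    n_acyls  = c("14:0", "16:0", "16:1", "18:0", "18:1", "19:0", "20:0",
                 "22:0", "24:0", "24:1", "26:0", "26:1")
  )
}

.db_row <- function(name, is_standard = FALSE) {
  sp <- parse_shorthand(name)
  mass <- species_mass(sp)
  info <- lipid_classes()
  info <- info[info$class == sp$lipid_class, ]
  comp <- elemental_composition(sp)
  mz_neg <- if (info$molecular && sp$level == "molecular")
    adduct_mz(mass, "[M-H]-") else NA_real_
  data.frame(
    name = sp$name, class = sp$lipid_class, level = sp$level,
    chains = sub("^\\S+ ", "", sp$name),
    carbons = sum(sp$chains$carbons),
    double_bonds = sum(sp$chains$double_bonds),
    n_carbon_atoms = unclass(comp)[["C"]],
    formula = format(comp), mass = mass,
    mz_quant = adduct_mz(mass, info$adduct), mz_neg = mz_neg,
    scan_type = info$scan_type, extract = info$extract,
    is_standard = is_standard, stringsAsFactors = FALSE
  )
}

.pair_names <- function(cls, acyls) {
  n <- length(acyls)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  apply(idx, 1, function(ij) {
    # canonical order: ascending carbons, then double bonds
    cd <- do.call(rbind, lapply(acyls[ij], function(a)
      as.integer(strsplit(a, ":")[[1]])))
    cd <- cd[order(cd[, 1], cd[, 2]), , drop = FALSE]
    paste0(cls, " ", cd[1, 1], ":", cd[1, 2], "/", cd[2, 1], ":", cd[2, 2])
  })
}

.sum_names <- function(cls, carbons, double_bonds, min_carbons = 0L) {
  grid <- expand.grid(c = carbons, d = double_bonds)
  grid <- grid[grid$d <= grid$c / 2 & grid$c >= min_carbons, ]
  paste0(cls, " ", grid$c, ":", grid$d)
}

#' Build the target species database
#'
#' Enumerates every species of the supported classes over a finite chain
#' space and returns one row per species with canonical name, sum carbons and
#' double bonds, elemental formula, monoisotopic mass, the precursor m/z in
#' the class' quantification channel (class-specific adduct) and, for
#' molecular-species phospholipids, the negative-mode `[M-H]-` precursor m/z
#' used by fatty-acyl scans. Rows are sorted by class then target m/z and
#' names are unique.
#'
#' @param chain_space As from [default_chain_space()]; any component may be
#'   replaced to restrict or extend the enumeration.
#' @param standards Optional internal-standard table (see
#'   [default_internal_standards()]); its species are appended and flagged.
#' @return A data.frame of class `species_db`.
#' @examples
#' db <- build_species_database()
#' subset(db, name %in% c("TAG 54:5", "PC 16:0/22:6"))
#' @export
build_species_database <- function(chain_space = default_chain_space(),
                                   standards = NULL) {
  names_all <- c(
    if (length(chain_space$pl_acyls))
      unlist(lapply(c("PC", "PE", "PS"), .pair_names,
                    acyls = chain_space$pl_acyls)),
    if (length(chain_space$ether))
      c(.sum_names("PC-O", chain_space$ether$carbons,
                   chain_space$ether$double_bonds, 4L),
        .sum_names("PE-O", chain_space$ether$carbons,
                   chain_space$ether$double_bonds, 4L)),
    if (length(chain_space$tag))
      .sum_names("TAG", chain_space$tag$carbons,
                 chain_space$tag$double_bonds, 6L),
    if (length(chain_space$dag))
      .sum_names("DAG", chain_space$dag$carbons,
                 chain_space$dag$double_bonds, 4L),
    if (length(chain_space$ce_acyls)) paste("CE", chain_space$ce_acyls),
    if (length(chain_space$n_acyls)) c(paste("CER", chain_space$n_acyls),
                                       paste("SM", chain_space$n_acyls))
  )
  names_all <- unique(names_all)
  db <- do.call(rbind, lapply(names_all, .db_row))
  if (is.null(db))
    db <- .db_row("PC 16:0/16:0")[0, ]
  if (!is.null(standards)) db <- add_standards(db, standards)
  db <- db[order(match(db$class, .CLASS_NAMES), db$mz_quant), ]
  rownames(db) <- NULL
  if (anyDuplicated(db$name)) stop("duplicate canonical names in database")
  class(db) <- c("species_db", "data.frame")
  db
}

#' Default internal-standard table
#'
#' One non-endogenous, odd- or short-chain standard per quantified class with
#' its spiked amount per sample (nmol). The ether classes are quantified
#' against the diacyl standard of their parent class: PC-O against the PC
#' standard and PE-O against the PE standard (the ether-PE response factor
#' exists precisely because ether-PE is read against the diacyl-PE standard).
#'
#' @return A data.frame with columns `class`, `species`, `amount_nmol`.
#' @export
default_internal_standards <- function() {
  data.frame(
    class = .CLASS_NAMES,
    species = c("CER 17:0", "SM 12:0", "DAG 28:0", "TAG 51:0", "CE 17:0",
                "PC 13:0/13:0", "PC 13:0/13:0", "PE 17:0/17:0",
                "PE 17:0/17:0", "PS 17:0/17:0"),
    amount_nmol = c(0.05, 0.2, 0.5, 2.5, 0.1, 2.5, 2.5, 1.0, 1.0, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Append internal-standard species to a database
#'
#' @param db A `species_db`.
#' @param standards A table as from [default_internal_standards()].
#' @return The database with standard species appended and flagged.
#' @export
add_standards <- function(db, standards) {
  new <- setdiff(unique(standards$species), db$name)
  if (length(new)) {
    db <- rbind(db, do.call(rbind, lapply(new, .db_row, is_standard = TRUE)))
  }
  db$is_standard[db$name %in% standards$species] <- TRUE
  class(db) <- c("species_db", "data.frame")
  db
}

#' Write / read a species database as CSV
#'
#' @param db A `species_db`.
#' @param path File path.
#' @return `read_species_db` returns the database; `write_species_db` its
#'   path, invisibly.
#' @export
write_species_db <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_db
#' @export
read_species_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(db) <- c("species_db", "data.frame")
  db
}

# Positive-mode channels quantify at sum-composition level: molecular
# species sharing a sum composition are isobaric and collapse onto one
# target. Returns one row per target with the sum name used for matching.
.channel_targets <- function(db, scan_type, extract) {
  sel <- db[db$scan_type == scan_type & db$extract == extract, , drop = FALSE]
  if (nrow(sel) == 0) return(sel[, c("name", "class")][0, ])
  key <- paste(sel$class, paste0(sel$carbons, ":", sel$double_bonds))
  # SM/CER names already denote the N-acyl, not the backbone total
  key[sel$class %in% c("SM", "CER")] <- sel$name[sel$class %in% c("SM", "CER")]
  agg <- !duplicated(key)
  out <- data.frame(
    target = key[agg], class = sel$class[agg],
    carbons = sel$n_carbon_atoms[agg],
    sum_carbons = sel$carbons[agg], sum_double_bonds = sel$double_bonds[agg],
    mz = sel$mz_quant[agg],
    is_standard = vapply(split(sel$is_standard, key)[key[agg]], any, logical(1)),
    stringsAsFactors = FALSE
  )
  out[order(out$mz), ]
}

#' Resolve an ambiguous ether / odd-chain mass assignment
#'
#' At unit resolution an ether-linked species and an odd-chain diacyl species
#' of the same class are nearly isobaric (CH4 vs O, 0.036 Th apart). When a
#' candidate mass matches both interpretations within tolerance, the
#' ether-linked species is assigned; internal-standard species (deliberately
#' odd-chain) are exempt. The decision is reported via `message()`.
#'
#' @param mass Candidate ion m/z (Th).
#' @param db A `species_db`.
#' @param scan_type,extract Channel the candidate was observed in.
#' @param tol Matching tolerance in Th.
#' @return The assigned target name, or `NA_character_` when nothing matches.
#' @examples
#' db <- build_species_database()
#' @export
assign_ether_or_odd <- function(mass, db, scan_type = "hg184",
                                extract = "total", tol = 0.3) {
  targets <- .channel_targets(db, scan_type, extract)
  hits <- targets[abs(targets$mz - mass) <= tol, , drop = FALSE]
  if (nrow(hits) == 0) return(NA_character_)
  ether <- hits$class %in% c("PC-O", "PE-O")
  odd <- hits$sum_carbons %% 2 == 1 & !hits$is_standard & !ether
  if (any(ether) && any(odd)) {
    pick <- hits$target[ether][which.min(abs(hits$mz[ether] - mass))]
    message("ambiguous ether/odd-chain mass ", format(mass), ": assigned ",
            pick, " over ", paste(hits$target[odd], collapse = ", "))
    return(pick)
  }
  hits$target[which.min(abs(hits$mz - mass))]
}
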