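# Lipid shorthand nomenclature: class definitions, parsing/formatting of
# species names ("PC 16:0/22:6", "TAG 54:5", "SM 18:0"), fatty-acyl
# classification, and per-species elemental compositions.

.CLASS_NAMES <- c("CER", "SM", "DAG", "TAG", "CE", "PC", "PC-O", "PE", "PE-O", "PS")

# class scaffold = head group + backbone with free linkage positions; chains
# are added as ester (C_c H_{2c-2d-2} O) / alkyl (C_c H_{2c-2d}) / N-acyl
# (same formula as ester) contributions
.CLASS_SCAFFOLD <- list(
  CER    = c(C = 18, H = 37, N = 1, O = 2, P = 0),  # sphingosine d18:1
  SM     = c(C = 23, H = 49, N = 2, O = 5, P = 1),  # sphingosine + P-choline
  DAG    = c(C = 3,  H = 8,  N = 0, O = 3, P = 0),  # glycerol
  TAG    = c(C = 3,  H = 8,  N = 0, O = 3, P = 0),
  CE     = c(C = 27, H = 46, N = 0, O = 1, P = 0),  # cholesterol
  PC     = c(C = 8,  H = 20, N = 1, O = 6, P = 1),  # glycerophosphocholine
  `PC-O` = c(C = 8,  H = 20, N = 1, O = 6, P = 1),
  PE     = c(C = 5,  H = 14, N = 1, O = 6, P = 1),  # glycerophosphoethanolamine
  `PE-O` = c(C = 5,  H = 14, N = 1, O = 6, P = 1),
  PS     = c(C = 6,  H = 14, N = 1, O = 8, P = 1)   # glycerophosphoserine
)

#' Lipid class definitions
#'
#' One row per supported class: backbone rule, number of chains, ether
#' linkage, the acquisition channel each class is quantified from (scan type,
#' polarity, extract) and the positive-mode precursor adduct. Sphingolipids
#' (CER, SM) are read from the hydrolyzed extract; all other classes from the
#' total extract. TAG, DAG and CE are reported at sum-composition level only;
#' PC, PE and PS support molecular-species resolution; ether classes (PC-O,
#' PE-O) are carried at sum level.
#'
#' @return A data.frame with columns `class`, `backbone`, `n_chains`,
#'   `ether`, `scan_type`, `extract`, `adduct`, `molecular`.
#' @export
lipid_classes <- function() {
  data.frame(
    class     = .CLASS_NAMES,
    backbone  = c("sphingoid-d18:1", "sphingoid-d18:1", "glycerol", "glycerol",
                  "sterol", "glycerol", "glycerol", "glycerol", "glycerol",
                  "glycerol"),
    n_chains  = c(1L, 1L, 2L, 3L, 1L, 2L, 2L, 2L, 2L, 2L),
    ether     = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                  FALSE),
    scan_type = c("cls_CER", "hg184", "cls_DAG", "cls_TAG", "cls_CE", "hg184",
                  "hg184", "nl141", "nl141", "cls_PS"),
    extract   = c("hydrolyzed", "hydrolyzed", "total", "total", "total",
                  "total", "total", "total", "total", "total"),
    adduct    = c("[M+H]+", "[M+H]+", "[M+NH4]+", "[M+NH4]+", "[M+NH4]+",
                  "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+"),
    molecular = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  TRUE),
    stringsAsFactors = FALSE
  )
}

#' Construct a fatty acyl chain
#'
#' @param carbons Chain carbon count (>= 2).
#' @param double_bonds Number of C=C double bonds (0 <= D <= C/2).
#' @param ether Logical; alkyl/alkenyl (non-ester) linkage.
#' @return A list of class `fatty_acyl`.
#' @export
fatty_acyl <- function(carbons, double_bonds, ether = FALSE) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || is.na(double_bonds))
    stop("malformed chain numbers")
  if (carbons < 2) stop("chain must have at least 2 carbons")
  if (double_bonds < 0 || double_bonds > carbons / 2)
    stop("double bonds must satisfy 0 <= D <= C/2")
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 ether = isTRUE(ether)),
            class = "fatty_acyl")
}

#' @export
format.fatty_acyl <- function(x, ...) {
  paste0(if (x$ether) "O-" else "", x$carbons, ":", x$double_bonds)
}

#' @export
print.fatty_acyl <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.chain_df <- function(chains) {
  data.frame(
    carbons      = vapply(chains, function(ch) ch$carbons, integer(1)),
    double_bonds = vapply(chains, function(ch) ch$double_bonds, integer(1)),
    ether        = vapply(chains, function(ch) ch$ether, logical(1))
  )
}

.new_species <- function(lipid_class, level, chains) {
  cls <- lipid_classes()
  info <- cls[cls$class == lipid_class, ]
  sp <- structure(list(lipid_class = lipid_class, level = level,
                       chains = chains, backbone = info$backbone),
                  class = "lipid_species")
  sp$name <- format(sp)
  sp
}

#' @export
format.lipid_species <- function(x, ...) {
  ch <- x$chains
  if (nrow(ch) == 0) return(x$lipid_class)
  if (x$level == "molecular" && x$lipid_class %in% c("PC", "PE", "PS")) {
    body <- paste(paste0(ch$carbons, ":", ch$double_bonds), collapse = "/")
  } else {
    body <- paste0(sum(ch$carbons), ":", sum(ch$double_bonds))
  }
  paste(x$lipid_class, body)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(x$name, " [", x$lipid_class, ", ", x$level, " level]\n", sep = "")
  invisible(x)
}

.normalise_class_token <- function(token) {
  token <- toupper(token)
  token <- sub("\\(O\\)$", "-O", token)
  token <- sub("^O-", "", token)
  token
}

#' Parse a lipid shorthand name
#'
#' Accepts `"<CLASS> <C>:<D>"` (sum composition) or
#' `"<CLASS> <C1>:<D1>/<C2>:<D2>"` (molecular species). Class tokens may use
#' the `"PC(O)"` or `"PC-O"` spelling for ether classes. SM and CER names
#' denote only the N-linked acyl; the sphingoid backbone d18:1 is implicit.
#' TAG, DAG and CE are always sum level.
#'
#' @param name A shorthand string, e.g. `"PC 16:0/22:6"` or `"TAG 54:5"`.
#' @return A `lipid_species` object.
#' @examples
#' parse_shorthand("PC 16:0/22:6")
#' parse_shorthand("TAG 54:5")
#' parse_shorthand("SM 18:0")
#' @export
parse_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  m <- regexec("^\\s*([A-Za-z]+(?:-O|\\(O\\))?)\\s+(\\d+):(\\d+)(?:/(\\d+):(\\d+))?\\s*$",
               name)
  parts <- regmatches(name, m)[[1]]
  if (length(parts) == 0)
    stop("cannot parse lipid name: '", name, "'")
  cls <- .normalise_class_token(parts[2])
  if (!cls %in% .CLASS_NAMES)
    stop("unsupported lipid class token: '", parts[2], "'")
  info <- lipid_classes()
  info <- info[info$class == cls, ]
  molecular_form <- parts[5] != ""
  if (molecular_form) {
    if (!info$molecular)
      stop(cls, " species are reported at sum-composition level only")
    ch <- list(fatty_acyl(parts[3], parts[4]), fatty_acyl(parts[5], parts[6]))
    ch <- ch[order(vapply(ch, `[[`, integer(1), "carbons"),
                   vapply(ch, `[[`, integer(1), "double_bonds"))]
    return(.new_species(cls, "molecular", .chain_df(ch)))
  }
  c_tot <- as.integer(parts[3]); d_tot <- as.integer(parts[4])
  if (cls %in% c("SM", "CER")) {
    # the single N-acyl chain is fully specified by the name
    return(.new_species(cls, "molecular",
                        .chain_df(list(fatty_acyl(c_tot, d_tot)))))
  }
  if (cls == "CE") {
    return(.new_species(cls, "sum", .chain_df(list(fatty_acyl(c_tot, d_tot)))))
  }
  if (c_tot < 2 * info$n_chains)
    stop("total carbons too small for a ", info$n_chains, "-chain species")
  if (d_tot < 0 || d_tot > c_tot / 2) stop("invalid double-bond count")
  ch <- data.frame(carbons = c_tot, double_bonds = d_tot, ether = info$ether)
  .new_species(cls, "sum", ch)
}

#' Default omega-family lookup for fatty acyls
#'
#' Shorthand `C:D` notation cannot encode double-bond positions, so the n-3 /
#' n-6 family of a chain is assigned from a configurable lookup keyed by
#' `"C:D"`. The default covers the common mammalian PUFA, assigning 22:5 (the
#' ambiguous case) to n-3 (docosapentaenoic acid, the dominant isomer in
#' rodent muscle).
#'
#' @return Named character vector mapping `"C:D"` to a family label.
#' @export
default_omega_table <- function() {
  c("18:2" = "n-6", "18:3" = "n-3", "20:3" = "n-6", "20:4" = "n-6",
    "20:5" = "n-3", "22:4" = "n-6", "22:5" = "n-3", "22:6" = "n-3")
}

#' Classify a fatty acyl chain
#'
#' A chain is a PUFA iff it has at least two double bonds; this is a pure
#' function of the double-bond count and is never affected by the omega
#' lookup. The omega family comes from `table`, `"unassigned"` on a miss.
#'
#' @param chain A `fatty_acyl`.
#' @param table Omega lookup, as from [default_omega_table()].
#' @return List with elements `is_pufa` and `omega_family`.
#' @examples
#' classify_acyl(fatty_acyl(22, 6))   # PUFA, n-3
#' classify_acyl(fatty_acyl(18, 1))   # not a PUFA
#' @export
classify_acyl <- function(chain, table = default_omega_table()) {
  key <- paste0(chain$carbons, ":", chain$double_bonds)
  fam <- if (key %in% names(table)) unname(table[[key]]) else "unassigned"
  list(is_pufa = chain$double_bonds >= 2L, omega_family = fam)
}

#' Count PUFA chains of a molecular-species diacyl phospholipid
#'
#' @param species A molecular-level PC, PE or PS `lipid_species`.
#' @return Integer 0, 1 or 2: number of chains with >= 2 double bonds.
#' @examples
#' count_pufa_chains(parse_shorthand("PC 18:2/22:6"))  # 2
#' @export
count_pufa_chains <- function(species) {
  if (!inherits(species, "lipid_species"))
    stop("expected a lipid_species")
  if (species$level != "molecular" || !species$lipid_class %in% c("PC", "PE", "PS"))
    stop("PUFA chains can only be counted on molecular-level diacyl ",
         "phospholipids; got ", species$name, " at ", species$level, " level")
  sum(species$chains$double_bonds >= 2L)
}

#' Elemental composition of a lipid species
#'
#' Assembles the class scaffold (head group + backbone) with one contribution
#' per chain: ester and N-acyl linkages add `C_c H_{2c-2d-2} O`, alkyl (ether)
#' linkages add `C_c H_{2c-2d}` with no oxygen. Sum-level species use the
#' total carbons/double bonds on the class scaffold with the class' number of
#' ester positions (one replaced by an ether linkage for PC-O/PE-O).
#'
#' @param species A `lipid_species`.
#' @return An `elemental_composition`.
#' @examples
#' elemental_composition(parse_shorthand("PC 16:0/18:1"))  # C42H82NO8P
#' @export
elemental_composition <- function(species) {
  scaf <- .CLASS_SCAFFOLD[[species$lipid_class]]
  comp <- composition(scaf[["C"]], scaf[["H"]], scaf[["N"]], scaf[["O"]],
                      scaf[["P"]])
  ch <- species$chains
  if (nrow(ch) == 0) return(comp)
  info <- lipid_classes()
  info <- info[info$class == species$lipid_class, ]
  if (species$level == "molecular" &&
      species$lipid_class %in% c("PC", "PE", "PS", "SM", "CER")) {
    for (i in seq_len(nrow(ch))) {
      add <- if (ch$ether[i]) {
        composition(C = ch$carbons[i], H = 2 * ch$carbons[i] - 2 * ch$double_bonds[i])
      } else {
        composition(C = ch$carbons[i],
                    H = 2 * ch$carbons[i] - 2 * ch$double_bonds[i] - 2, O = 1)
      }
      comp <- comp + add
    }
    return(comp)
  }
  c_tot <- sum(ch$carbons); d_tot <- sum(ch$double_bonds)
  n_ester <- info$n_chains - as.integer(info$ether)
  comp + composition(C = c_tot, H = 2 * c_tot - 2 * d_tot - 2 * n_ester,
                     O = n_ester)
}

#' Monoisotopic mass of a lipid species
#'
#' @param species A `lipid_species`.
#' @return Neutral monoisotopic mass in Da.
#' @export
species_mass <- function(species) {
  monoisotopic_mass(elemental_composition(species))
}

#' m/z of a fatty-acyl carboxylate fragment
#'
#' Negative-mode precursor ion scans select species yielding the `[FA - H]-`
#' carboxylate; this is that fragment's m/z.
#'
#' @param chain A `fatty_acyl`.
#' @return m/z in Th (e.g. 255.2330 for 16:0).
#' @export
carboxylate_mz <- function(chain) {
  fa <- composition(C = chain$carbons,
                    H = 2 * chain$carbons - 2 * chain$double_bonds, O = 2)
  adduct_mz(monoisotopic_mass(fa), "[M-H]-")
}
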