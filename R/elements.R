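# Elemental bookkeeping for lipid species: compositions are named integer
# vectors over C/H/N/O/P, masses are monoisotopic, and isotope envelopes are
# either a carbon-only binomial or a full multi-element convolution.

ELEMENTS <- c("C", "H", "N", "O", "P")

# monoisotopic masses of the principal (lightest) isotopes
.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

.PROTON_MASS  <- 1.007276467
.NH4_MASS     <- 18.033823       # [M+NH4]+ adduct addition
.C13_C12_DIFF <- 1.0033548378    # nominal +1 isotopologue spacing

# per-element isotope tables: nominal mass shift (0/1/2) and abundance
.ISOTOPES <- list(
  C = data.frame(shift = c(0L, 1L), abundance = c(0.9893, 0.0107)),
  H = data.frame(shift = c(0L, 1L), abundance = c(0.999885, 0.000115)),
  N = data.frame(shift = c(0L, 1L), abundance = c(0.99636, 0.00364)),
  O = data.frame(shift = c(0L, 1L, 2L), abundance = c(0.99757, 0.00038, 0.00205)),
  P = data.frame(shift = 0L, abundance = 1.0)
)

#' Construct an elemental composition
#'
#' Compositions are named integer vectors over the elements C, H, N, O and P.
#' They add element-wise; a molecular species' composition is head group +
#' backbone + chains minus the condensation water implied by each linkage.
#'
#' @param C,H,N,O,P Non-negative integer atom counts.
#' @return A named integer vector of class `elemental_composition`.
#' @examples
#' composition(C = 3, H = 8, O = 3)  # glycerol
#' @export
composition <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  x <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(x < 0)) stop("atom counts must be non-negative")
  structure(as.integer(x), names = ELEMENTS, class = "elemental_composition")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  structure(unclass(e1) + unclass(e2), names = ELEMENTS,
            class = "elemental_composition")
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  structure(unclass(e1) - unclass(e2), names = ELEMENTS,
            class = "elemental_composition")
}

#' @export
format.elemental_composition <- function(x, ...) {
  n <- unclass(x)
  paste0(ELEMENTS[n > 0], n[n > 0], collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp An `elemental_composition`.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  sum(unclass(comp) * .MONO_MASS[ELEMENTS])
}

#' Ion m/z for a neutral monoisotopic mass under a singly charged adduct
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param adduct One of `"[M+H]+"`, `"[M+NH4]+"`, `"[M-H]-"`.
#' @return m/z in Th.
#' @export
adduct_mz <- function(mass, adduct = c("[M+H]+", "[M+NH4]+", "[M-H]-")) {
  adduct <- match.arg(adduct)
  switch(adduct,
    "[M+H]+"   = mass + .PROTON_MASS,
    "[M+NH4]+" = mass + .NH4_MASS,
    "[M-H]-"   = mass - .PROTON_MASS
  )
}

#' Isotopologue envelope fractions
#'
#' Absolute probabilities of the M+0 .. M+`kmax` isotopologues of a species.
#' The `"binomial"` model considers only carbon (13C abundance `p13c`), the
#' community-standard approximation at unit resolution; `"convolution"`
#' convolves the full isotope distributions of C, H, N and O and is used as
#' the exact reference. Fractions are not renormalised, so the M+0 fraction
#' of the binomial model is exactly `(1 - p13c)^nC`.
#'
#' @param comp An `elemental_composition` (the carbon count alone suffices
#'   for the binomial model).
#' @param kmax Highest isotopologue index returned (default 4).
#' @param model `"binomial"` or `"convolution"`.
#' @param p13c 13C natural abundance used by the binomial model.
#' @return Numeric vector of length `kmax + 1`, fractions of M+0 .. M+kmax.
#' @examples
#' env <- isotope_envelope(composition(C = 42, H = 82, N = 1, O = 8, P = 1))
#' env[1]  # M+0 fraction, (1 - 0.0107)^42
#' @export
isotope_envelope <- function(comp, kmax = 4L,
                             model = c("binomial", "convolution"),
                             p13c = 0.0107) {
  model <- match.arg(model)
  if (model == "binomial") {
    nc <- unclass(comp)[["C"]]
    return(stats::dbinom(0:kmax, size = nc, prob = p13c))
  }
  out <- c(1, rep(0, kmax))
  for (el in ELEMENTS) {
    n <- unclass(comp)[[el]]
    if (n == 0) next
    iso <- .ISOTOPES[[el]]
    single <- rep(0, kmax + 1)
    single[iso$shift + 1L] <- iso$abundance
    out <- .conv_trunc(out, .poly_power(single, n, kmax), kmax)
  }
  out
}

# truncated polynomial product of two shift distributions
.conv_trunc <- function(a, b, kmax) {
  out <- rep(0, kmax + 1)
  for (i in seq_along(a)) {
    j <- seq_len(kmax + 2L - i)
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

# distribution of n iid atoms by exponentiation-by-squaring
.poly_power <- function(single, n, kmax) {
  result <- c(1, rep(0, kmax))
  base <- single
  while (n > 0) {
    if (n %% 2 == 1) result <- .conv_trunc(result, base, kmax)
    base <- .conv_trunc(base, base, kmax)
    n <- n %/% 2
  }
  result
}
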