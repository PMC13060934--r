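# Molecular-formula arithmetic and monoisotopic mass / m/z computation.
#
# Formulas are represented as named integer vectors (element symbol -> count,
# absent elements omitted, all counts >= 1) and rendered in Hill order
# (C first, then H, then the remaining elements alphabetically).

# Monoisotopic atomic masses in Da (mass of the most abundant isotope,
# IUPAC/CODATA values). Carbon defines the scale and is exactly 12.
.MONO_MASS <- c(
  C = 12.000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706900,
  P = 30.9737615100
)

# Mass of the proton (Da); the [M+H]+ adduct adds a proton, not a hydrogen
# atom (the electron stays behind).
.PROTON_MASS <- 1.007276466

#' Monoisotopic mass constants
#'
#' Returns the monoisotopic atomic masses (Da) used for all mass arithmetic,
#' plus the proton mass used for the \eqn{[M+H]^+} adduct.
#'
#' @return A list with elements `atomic` (named numeric vector of
#'   monoisotopic masses, Da) and `proton` (proton mass, Da).
#' @examples
#' mass_constants()$atomic[["C"]] # exactly 12
#' @export
mass_constants <- function() {
  list(atomic = .MONO_MASS, proton = .PROTON_MASS)
}

#' Parse a molecular formula in Hill notation
#'
#' Parses strings such as `"C22H44N4O3"` or `"H2O"` into a named integer
#' count vector. An omitted count means 1 (`"CO2"` is one carbon, two
#' oxygens). Supported elements are C, H, N, O, S and P.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts, in Hill order.
#' @examples
#' parse_formula("C22H44N4O3")
#' parse_formula("CO2")
#' @seealso [render_formula()] for the inverse.
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula: ", sQuote(text))
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), suppressWarnings(as.integer(cnt)), 1L)
  bad <- setdiff(sym, names(.MONO_MASS))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(is.na(cnt)) || any(cnt <= 0L)) {
    stop("element counts must be positive integers in ", sQuote(text))
  }
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  .hill_sort(out)
}

# Order a count vector in Hill convention: C, H, then alphabetical.
.hill_sort <- function(counts) {
  sym <- names(counts)
  rest <- sort(setdiff(sym, c("C", "H")))
  ord <- c(intersect(c("C", "H"), sym), rest)
  counts[ord]
}

# Coerce a formula argument: accept a Hill string or a named count vector.
.as_formula <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop("formula count vector must be fully named")
  }
  f <- f[f != 0]
  if (any(f < 0)) stop("negative element count")
  bad <- setdiff(names(f), names(.MONO_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  storage.mode(f) <- "integer"
  .hill_sort(f)
}

#' Render a molecular formula in Hill notation
#'
#' @param counts Named integer vector of element counts (or a formula string,
#'   which is canonicalized).
#' @return A single Hill-order formula string; counts of 1 are omitted.
#' @examples
#' render_formula(c(O = 1, H = 2)) # "H2O"
#' @export
render_formula <- function(counts) {
  counts <- .as_formula(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the monoisotopic atomic mass.
#'
#' @param f Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  sum(.MONO_MASS[names(f)] * f)
}

#' Protonated m/z of a formula
#'
#' The \eqn{[M+H]^+} ion observed in positive-mode electrospray ionization:
#' neutral monoisotopic mass plus the proton mass (1.007276 Da).
#'
#' @inheritParams monoisotopic_mass
#' @return m/z of the singly protonated ion.
#' @examples
#' protonated_mz("C6H14N4O2") # arginine, 175.1189
#' @export
protonated_mz <- function(f) {
  monoisotopic_mass(f) + .PROTON_MASS
}

# Element-wise sum of two count vectors.
.formula_add <- function(a, b) {
  sym <- union(names(a), names(b))
  out <- integer(length(sym))
  names(out) <- sym
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .hill_sort(out[out != 0L])
}

# Element-wise difference a - b; errors if any count would go negative.
.formula_subtract <- function(a, b, context = "formula subtraction") {
  sym <- union(names(a), names(b))
  out <- integer(length(sym))
  names(out) <- sym
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L)) {
    stop(context, " would require negative ",
         paste(names(out)[out < 0L], collapse = ", "), " count")
  }
  .hill_sort(out[out != 0L])
}

#' Amide condensation of an amine with a fatty acid
#'
#' N-acyl amides form by condensation of the fatty-acid carboxyl with the
#' amine nitrogen, losing one water: the product formula is the element-wise
#' sum minus H2O. Exactly one water is removed per conjugate, so each
#' (amine, fatty acid) pair yields one product regardless of additional
#' functional groups on the amine.
#'
#' @param amine Formula of the amine (must contain at least one N and two H).
#' @param fatty_acid Formula of the fatty acid (must contain a carboxyl:
#'   at least two O and one H).
#' @return Named count vector of the conjugate formula.
#' @examples
#' render_formula(condense_amide("C6H14N4O2", "C16H32O2")) # palmitoyl arginine
#' @export
condense_amide <- function(amine, fatty_acid) {
  amine <- .as_formula(amine)
  fatty_acid <- .as_formula(fatty_acid)
  if (is.na(amine["N"]) || amine["N"] < 1L || is.na(amine["H"]) || amine["H"] < 2L) {
    stop("amine must contain >= 1 N and >= 2 H: ", render_formula(amine))
  }
  if (is.na(fatty_acid["O"]) || fatty_acid["O"] < 2L ||
      is.na(fatty_acid["H"]) || fatty_acid["H"] < 1L) {
    stop("fatty acid must contain a carboxyl (>= 2 O, >= 1 H): ",
         render_formula(fatty_acid))
  }
  .formula_subtract(.formula_add(amine, fatty_acid), c(H = 2L, O = 1L),
                    context = "amide condensation")
}

#' Fatty primary amide of a fatty acid
#'
#' The fatty-acid diagnostic fragment of an N-acyl amide is the primary
#' amide of the fatty acid (e.g. palmitamide from palmitic acid):
#' FA + NH3 - H2O, i.e. net -1 O, +1 N, +1 H.
#'
#' @param fatty_acid Formula of the fatty acid (carboxyl required).
#' @return Named count vector of the primary amide formula.
#' @examples
#' render_formula(fatty_amide_formula("C16H32O2")) # "C16H33NO"
#' @export
fatty_amide_formula <- function(fatty_acid) {
  fatty_acid <- .as_formula(fatty_acid)
  if (is.na(fatty_acid["O"]) || fatty_acid["O"] < 2L ||
      is.na(fatty_acid["H"]) || fatty_acid["H"] < 1L) {
    stop("fatty acid must contain a carboxyl (>= 2 O, >= 1 H): ",
         render_formula(fatty_acid))
  }
  .formula_subtract(.formula_add(fatty_acid, c(N = 1L, H = 3L)),
                    c(H = 2L, O = 1L), context = "amide formation")
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z; must be positive.
#' @return Signed ppm error `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(500.0025, 500) # +5
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}
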