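# Elemental composition arithmetic and monoisotopic mass computation.
# Formulas are represented as named integer vectors (element -> count),
# e.g. c(C = 8L, H = 10L, N = 4L, O = 2L) for caffeine.

# Monoisotopic atomic masses (Da), most abundant isotope, CODATA/IUPAC.
ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Na = 22.9897692809,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Br = 78.9183371,
  I  = 126.904473
)

ELECTRON_MASS <- 0.00054857990
PROTON_MASS <- ATOMIC_MASS[["H"]] - ELECTRON_MASS
# C13 - C12 spacing used for isotope traces
ISOTOPE_SPACING <- 1.0033548378
CH2_MASS <- ATOMIC_MASS[["C"]] + 2 * ATOMIC_MASS[["H"]]

#' Parse a molecular formula string
#'
#' Converts a Hill-notation formula string such as `"C8H10N4O2"` into the
#' named integer vector representation used throughout the package. Named
#' numeric vectors pass through unchanged (after validation), so functions
#' taking formulas accept either form.
#'
#' @param x Formula string (e.g. `"C6H12O6"`) or named integer vector.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H10N4O2")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) && length(x) > 0)
      stop("numeric formula must be a named vector of element counts")
    x <- x[x != 0]
    bad <- setdiff(names(x), names(ATOMIC_MASS))
    if (length(bad) > 0) stop("unknown element(s): ", paste(bad, collapse = ", "))
    if (any(x < 0)) stop("negative element counts in formula")
    counts <- as.integer(x)
    names(counts) <- names(x)
    return(counts[order(names(counts))])
  }
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  if (x == "" || is.na(x)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: ", x)
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(els, names(ATOMIC_MASS))
  if (length(bad) > 0) stop("unknown element(s): ", paste(bad, collapse = ", "))
  agg <- tapply(cnt, els, sum)
  counts <- as.integer(agg)
  names(counts) <- names(agg)
  counts <- counts[order(names(counts))]
  counts[counts != 0]
}

#' Format a formula as a Hill-notation string
#'
#' @param f Formula (named vector or string).
#' @return Single string, carbon then hydrogen then other elements
#'   alphabetically; `""` for the empty formula.
#' @export
formula_to_string <- function(f) {
  f <- parse_formula(f)
  if (length(f) == 0) return("")
  hill <- c(intersect(c("C", "H"), names(f)), sort(setdiff(names(f), c("C", "H"))))
  f <- f[hill]
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element count times monoisotopic atomic mass.
#'
#' @param f Formula (named vector or string).
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("CH2")       # 14.01565
#' monoisotopic_mass("C8H10N4O2") # 194.0804
#' @export
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  if (length(f) == 0) return(0)
  sum(ATOMIC_MASS[names(f)] * f)
}

#' @rdname formula_arithmetic
#' @export
formula_add <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- integer(length(els)); names(out) <- els
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  parse_formula(out)
}

#' Formula arithmetic
#'
#' Element-wise addition, subtraction and containment of formulas.
#' Subtraction errors if any element count would become negative.
#'
#' @param a,b Formulas (named vectors or strings).
#' @name formula_arithmetic
#' @return `formula_add`/`formula_subtract` return a formula;
#'   `is_subformula` returns `TRUE` iff `a` is element-wise contained in `b`.
#' @export
formula_subtract <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- integer(length(els)); names(out) <- els
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("formula subtraction yields negative counts: ",
         formula_to_string(a), " - ", formula_to_string(b))
  parse_formula(out)
}

#' @rdname formula_arithmetic
#' @export
is_subformula <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  if (length(a) == 0) return(TRUE)
  if (!all(names(a) %in% names(b))) return(FALSE)
  all(a <= b[names(a)])
}

#' Ring and double bond equivalents
#'
#' RDBE = C + 1 + (N + P)/2 - (H + halogens)/2. Used to reject chemically
#' implausible fragment subformulas (RDBE < -0.5).
#'
#' @param f Formula.
#' @return RDBE value (may be half-integer).
#' @export
rdbe <- function(f) {
  f <- parse_formula(f)
  g <- function(el) if (el %in% names(f)) f[[el]] else 0L
  g("C") + 1 + (g("N") + g("P")) / 2 -
    (g("H") + g("F") + g("Cl") + g("Br") + g("I")) / 2
}

# Positive-mode adduct shift table: m/z = (neutral_mass + shift)/charge,
# electron mass folded into the shift.
ADDUCT_TABLE <- data.frame(
  adduct = c("[M+H]+", "[M+Na]+", "[M+K]+"),
  shift = c(ATOMIC_MASS[["H"]] - ELECTRON_MASS,
            ATOMIC_MASS[["Na"]] - ELECTRON_MASS,
            ATOMIC_MASS[["K"]] - ELECTRON_MASS),
  charge = c(1L, 1L, 1L),
  stringsAsFactors = FALSE
)

#' Adducts known to the package
#' @return Data frame with columns `adduct`, `shift` (Da), `charge`.
#' @export
adduct_table <- function() ADDUCT_TABLE

adduct_row <- function(adduct) {
  i <- match(adduct, ADDUCT_TABLE$adduct)
  if (is.na(i)) stop("unknown adduct: ", adduct)
  ADDUCT_TABLE[i, ]
}

#' Ion m/z of a neutral mass under an adduct
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param adduct Adduct label, e.g. `"[M+H]+"`; see [adduct_table()].
#' @return m/z in Th: `(neutral_mass + shift)/charge` with the electron mass
#'   accounted for in the shift.
#' @examples
#' adduct_mz(monoisotopic_mass("C8H10N4O2"), "[M+H]+") # 195.0877
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  a <- adduct_row(adduct)
  (neutral_mass + a$shift) / a$charge
}

#' Neutral mass from an observed adduct m/z
#'
#' Inverse of [adduct_mz()].
#'
#' @param mz Observed m/z (Th).
#' @param adduct Adduct label.
#' @return Neutral monoisotopic mass (Da).
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  a <- adduct_row(adduct)
  mz * a$charge - a$shift
}

ppm_diff <- function(observed, expected) (observed - expected) / expected * 1e6

#' Coarse isotope-envelope model for a formula
#'
#' Relative intensities of the M, M+1 and M+2 isotopologues from element
#' counts: M+1 dominated by 13C (1.08% per carbon, plus 0.37% per nitrogen),
#' M+2 by the squared-13C term plus 18O (0.205% per oxygen) and 34S (4.42%
#' per sulfur). Intended for simulated envelopes and MS1 isotope-correlation
#' scoring, not for fine isotope structure.
#'
#' @param f Formula.
#' @param n_isotopes Number of isotopologues to return (>= 1).
#' @return Numeric vector of relative intensities, first element 1.
#' @export
isotope_pattern <- function(f, n_isotopes = 3) {
  f <- parse_formula(f)
  g <- function(el) if (el %in% names(f)) f[[el]] else 0L
  p1 <- g("C") * 0.0108 + g("N") * 0.0037
  p2 <- p1^2 / 2 + g("O") * 0.00205 + g("S") * 0.0442
  pat <- c(1, p1, p2, p2 * p1)
  if (n_isotopes <= 4) pat[seq_len(n_isotopes)] else c(pat, rep(0, n_isotopes - 4))
}
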