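# most-abundant-isotope masses (u), CODATA/NIST atomic mass evaluation
MONOISOTOPIC_MASS <- c(
  H = 1.00782503207, D = 2.01410177785, C = 12.0, N = 14.0030740048,
  O = 15.9949146196, S = 31.97207100, P = 30.97376163, F = 18.99840322,
  Cl = 34.96885268, Br = 78.9183371, I = 126.904473, Si = 27.9769265325,
  B = 11.0093054, Na = 22.9897692809, K = 38.96370668, Li = 7.01600455,
  Ca = 39.96259098, Mg = 23.985041700, Fe = 55.9349375, Zn = 63.9291422,
  Cu = 62.9295975, Se = 79.9165213
)

PROTON_MASS <- 1.00727646688

#' Parse a Hill-notation molecular formula
#'
#' Accepts strings such as `"C58H69N6O12S3"` or `"H2O"`: element symbols
#' (one capital, optional lowercase) each followed by an optional count.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  formula <- gsub("[[:space:]]", "", formula)
  if (!nzchar(formula)) stop("empty molecular formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse molecular formula: ", formula, call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnts, syms, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of most-abundant-isotope masses over all atoms.
#'
#' @param formula Formula string or named count vector from
#'   [parse_formula()].
#' @return Mass in u.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("empty molecular formula", call. = FALSE)
  }
  sum(MONOISOTOPIC_MASS[names(counts)] * as.numeric(counts))
}

#' Monoisotopic \[M+H\]+ m/z from a molecular formula
#'
#' Two conventions are in circulation for the formula printed next to an
#' HRMS-ESI \[M+H\]+ value: it may denote the neutral molecule M (the
#' adduct proton is then added to the computed mass) or the
#' protonated-ion composition itself (the extra H is already in the
#' formula). With `protonated = TRUE` (default) the formula is taken as
#' the ion composition and the m/z is the plain atom sum; with
#' `protonated = FALSE` one proton mass (1.00727646688 u) is added to the
#' neutral monoisotopic mass. The two differ by the electron mass
#' (~0.00055 u); the ion-composition convention reproduces published
#' four-decimal calculated values for maleimide-linked cyanine tracer
#' conjugates, and is therefore the default.
#'
#' @param formula Formula string or named count vector.
#' @param protonated Whether `formula` already includes the adduct
#'   proton.
#' @return m/z of the singly protonated ion, in u per elementary charge.
#' @examples
#' monoisotopic_mh("C58H69N6O12S3")          # printed ion composition
#' monoisotopic_mh("H2O", protonated = FALSE)  # water + proton = 19.0178
#' @export
monoisotopic_mh <- function(formula, protonated = TRUE) {
  m <- monoisotopic_mass(formula)
  if (isTRUE(protonated)) m else m + PROTON_MASS
}
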