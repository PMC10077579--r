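#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (Da); 12C defines the scale exactly.
ELEMENT_MASS <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376200
)

# Mass of a proton; [M-H]- ions are lighter than the neutral by this amount.
PROTON_MASS <- 1.00727646

ELEMENTS <- c("C", "H", "N", "O", "S", "P")

#' Construct a table of molecular formulas
#'
#' Molecular formulas are represented throughout the package as data frames
#' with integer columns `C`, `H`, `N`, `O`, `S`, `P`, one row per formula.
#' All index functions ([dbe()], [ai_mod()], [nosc()], ...) are vectorised
#' over such tables.
#'
#' @param C,H,N,O,S,P integer element counts (recycled to a common length).
#' @return A data frame with columns `C`, `H`, `N`, `O`, `S`, `P`.
#' @details Formulas must describe neutral even-electron molecules: `C >= 1`,
#'   `H >= 1`, all counts non-negative integers.
#' @examples
#' molecular_formula(C = 6, H = 12, O = 6)  # glucose
#' @export
molecular_formula <- function(C, H, N = 0L, O = 0L, S = 0L, P = 0L) {
  f <- data.frame(C = C, H = H, N = N, O = O, S = S, P = P)
  validate_formula(f)
  f
}

validate_formula <- function(f) {
  if (!is.data.frame(f) || !all(ELEMENTS %in% names(f))) {
    stop("formula table must have columns C, H, N, O, S, P", call. = FALSE)
  }
  m <- as.matrix(f[ELEMENTS])
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  if (any(f$C < 1)) stop("formulas must contain at least one carbon (C >= 1)", call. = FALSE)
  if (any(f$H < 1)) stop("formulas must contain at least one hydrogen (H >= 1)", call. = FALSE)
  invisible(f)
}

#' Monoisotopic neutral mass of a formula
#'
#' @param f formula table (see [molecular_formula()]).
#' @return Numeric vector of exact masses in Da.
#' @examples
#' formula_mass(molecular_formula(6, 12, O = 6))  # 180.0634
#' @export
formula_mass <- function(f) {
  validate_formula(f)
  as.vector(as.matrix(f[names(ELEMENT_MASS)]) %*% ELEMENT_MASS)
}

#' Neutral mass of a singly charged deprotonated ion
#'
#' Converts a measured m/z of an [M-H]- ion (negative electrospray mode)
#' to the neutral monoisotopic mass by adding one proton mass.
#'
#' @param mz measured mass-to-charge ratio (Da), singly charged.
#' @param charge ion charge; only `-1` is supported.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz, charge = -1L) {
  if (length(charge) != 1L || charge != -1L) {
    stop("only singly charged [M-H]- ions (charge = -1) are supported", call. = FALSE)
  }
  mz + PROTON_MASS
}

#' Canonical formula strings
#'
#' The canonical text form lists all six elements in the fixed order
#' C, H, O, N, S, P with explicit counts (e.g. `"C10H12O5N1S0P0"`), so that
#' every formula has exactly one string representation. These strings are
#' used as column names of formula matrices and as join keys.
#'
#' @param f formula table.
#' @return Character vector of canonical strings.
#' @export
formula_string <- function(f) {
  validate_formula(f)
  paste0(
    "C", f$C, "H", f$H, "O", f$O, "N", f$N, "S", f$S, "P", f$P
  )
}

#' @rdname formula_string
#' @param x character vector of canonical formula strings.
#' @export
parse_formula <- function(x) {
  m <- regmatches(x, regexec("^C(\\d+)H(\\d+)O(\\d+)N(\\d+)S(\\d+)P(\\d+)$", x))
  bad <- vapply(m, length, 1L) != 7L
  if (any(bad)) {
    stop("not canonical formula strings: ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  counts <- t(vapply(m, function(g) as.integer(g[-1]), integer(6)))
  molecular_formula(
    C = counts[, 1], H = counts[, 2], O = counts[, 3],
    N = counts[, 4], S = counts[, 5], P = counts[, 6]
  )
}

# Deterministic ordering used wherever formulas are sorted: exact mass,
# ties broken by element counts (C, H, O, N, S, P).
formula_order <- function(f) {
  order(formula_mass(f), f$C, f$H, f$O, f$N, f$S, f$P)
}
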