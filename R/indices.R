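# Per-formula molecular indices. All functions are vectorised over formula
# tables (data frames with columns C, H, N, O, S, P).

#' Double bond equivalents
#'
#' Rings-plus-double-bonds of a neutral even-electron molecule:
#' `DBE = 1 + C - H/2 + N/2 + P/2`.
#'
#' @param f formula table.
#' @return Numeric vector; integer-valued and non-negative for chemically
#'   valid formulas.
#' @export
dbe <- function(f) {
  validate_formula(f)
  1 + f$C - f$H / 2 + f$N / 2 + f$P / 2
}

#' Aromaticity-corrected double bond equivalents (DBE_AI)
#'
#' The DBE of the molecular core after subtracting unsaturation that
#' heteroatom-bearing functional groups can contribute:
#' `DBE_AI = 1 + C - 0.5 O - S - 0.5 (N + P + H)`.
#' Values fall on a 0.5 grid and may be negative; DBE_AI is the numerator
#' of the modified aromaticity index.
#'
#' @param f formula table.
#' @return Numeric vector on the 0.5 grid.
#' @export
dbe_ai <- function(f) {
  validate_formula(f)
  1 + f$C - 0.5 * f$O - f$S - 0.5 * (f$N + f$P + f$H)
}

#' Modified aromaticity index (AI_mod)
#'
#' `AI_mod = DBE_AI / (C - 0.5 O - N - S - P)`, clamped to 0 whenever the
#' numerator or the denominator is <= 0. Values above 0.5 flag aromatic
#' structures; values above 0.67 condensed aromatics. AI_mod can exceed 1
#' for some combustion-derived cores, so no upper bound is imposed.
#'
#' @param f formula table.
#' @return Numeric vector, >= 0.
#' @export
ai_mod <- function(f) {
  num <- dbe_ai(f)
  den <- f$C - 0.5 * f$O - f$N - f$S - f$P
  out <- ifelse(num <= 0 | den <= 0, 0, num / den)
  pmax(out, 0)
}

#' Nominal oxidation state of carbon (NOSC)
#'
#' `NOSC = 4 - (4 C + H - 3 N - 2 O + 5 P - 2 S) / C` for a neutral
#' molecule. Higher values indicate more oxidised carbon, whose further
#' oxidation is thermodynamically more favourable.
#'
#' @param f formula table.
#' @return Numeric vector, typically in [-4, 4].
#' @export
nosc <- function(f) {
  validate_formula(f)
  4 - (4 * f$C + f$H - 3 * f$N - 2 * f$O + 5 * f$P - 2 * f$S) / f$C
}

#' Compound category and oxygen class of a formula
#'
#' Assigns each formula to exactly one of four descriptive compound
#' categories -- saturated (DBE = 0), aromatic (AI_mod > 0.5),
#' unsaturated (H/C >= 1.5), and highly unsaturated (AI_mod <= 0.5 and
#' H/C < 1.5) -- and to an oxygen class (O-rich: O/C >= 0.5; O-poor:
#' O/C < 0.5). Saturated is evaluated first and aromatic second so the
#' four categories partition formula space.
#'
#' @param f formula table.
#' @return Data frame with factor columns `category` and `oxygen_class`.
#' @export
classify_formula <- function(f) {
  d <- dbe(f)
  ai <- ai_mod(f)
  hc <- f$H / f$C
  category <- ifelse(
    d == 0, "saturated",
    ifelse(ai > 0.5, "aromatic",
      ifelse(hc >= 1.5, "unsaturated", "highly_unsaturated")
    )
  )
  data.frame(
    category = factor(category,
      levels = c("aromatic", "highly_unsaturated", "unsaturated", "saturated")
    ),
    oxygen_class = factor(ifelse(f$O / f$C >= 0.5, "O_rich", "O_poor"),
      levels = c("O_rich", "O_poor")
    )
  )
}

#' Full per-formula index table
#'
#' Joins all molecular indices, elemental ratios and categories for a set
#' of formulas; the standard companion table to an assignment result.
#'
#' @param f formula table.
#' @return Data frame with columns `formula`, element counts, `mass`,
#'   `dbe`, `dbe_ai`, `ai_mod`, `nosc`, `hc`, `oc`, `nc`, `category`,
#'   `oxygen_class`.
#' @export
formula_indices <- function(f) {
  validate_formula(f)
  cbind(
    data.frame(formula = formula_string(f)),
    f[ELEMENTS],
    data.frame(
      mass = formula_mass(f),
      dbe = dbe(f),
      dbe_ai = dbe_ai(f),
      ai_mod = ai_mod(f),
      nosc = nosc(f),
      hc = f$H / f$C,
      oc = f$O / f$C,
      nc = f$N / f$C
    ),
    classify_formula(f)
  )
}

#' Default degradation-index reference formulas
#'
#' The degradation index is an intensity ratio over ten reference CHO
#' formulas: five whose relative abundance increases with diagenetic
#' alteration (the numerator set) and five associated with fresh DOM.
#' The shipped set is read from `inst/extdata/ideg_formulas.csv` and can
#' be replaced by any user-supplied disjoint pair of formula sets.
#'
#' @return List with formula tables `neg` (degradation-enriched, numerator)
#'   and `pos` (fresh).
#' @export
ideg_reference_sets <- function() {
  path <- system.file("extdata", "ideg_formulas.csv", package = "domdiv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(
    neg = parse_formula(tab$formula[tab$set == "neg"]),
    pos = parse_formula(tab$formula[tab$set == "pos"])
  )
}

#' Degradation index of a sample
#'
#' `I_Deg = sum(I_neg) / (sum(I_neg) + sum(I_pos))` over the intensities of
#' the two reference formula sets in a sample. Low values indicate fresh,
#' little-degraded DOM.
#'
#' @param sample an `assigned_sample` (see [assign_sample()]) or a named
#'   numeric vector of intensities keyed by canonical formula string.
#' @param neg_set,pos_set formula tables of the numerator (degradation)
#'   and denominator-only (fresh) reference sets; default the shipped set.
#' @return A single value in [0, 1], or `NA` with a warning when no
#'   reference formula is present in the sample.
#' @export
i_deg <- function(sample, neg_set = NULL, pos_set = NULL) {
  if (is.null(neg_set) || is.null(pos_set)) {
    ref <- ideg_reference_sets()
    if (is.null(neg_set)) neg_set <- ref$neg
    if (is.null(pos_set)) pos_set <- ref$pos
  }
  neg_keys <- formula_string(neg_set)
  pos_keys <- formula_string(pos_set)
  if (any(neg_keys %in% pos_keys)) {
    stop("neg_set and pos_set must be disjoint", call. = FALSE)
  }
  ints <- sample_intensity_by_formula(sample)
  s_neg <- sum(ints[names(ints) %in% neg_keys])
  s_pos <- sum(ints[names(ints) %in% pos_keys])
  if (s_neg + s_pos == 0) {
    warning("no degradation-index reference formula detected; I_Deg undefined")
    return(NA_real_)
  }
  s_neg / (s_neg + s_pos)
}

# Accepts an assigned_sample or a named intensity vector and returns summed
# intensity per canonical formula string.
sample_intensity_by_formula <- function(sample) {
  if (inherits(sample, "assigned_sample")) {
    a <- sample$assignments
    tapply(a$intensity, a$formula, sum)
  } else if (is.numeric(sample) && !is.null(names(sample))) {
    tapply(sample, names(sample), sum)
  } else {
    stop("sample must be an assigned_sample or a named intensity vector", call. = FALSE)
  }
}
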