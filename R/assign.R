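# CHNOSP molecular formula assignment for singly charged [M-H]- ions.
#
# Candidate generation enumerates all element-count combinations inside the
# configured ranges whose exact mass matches the neutralised measurement
# within a ppm tolerance; chemical plausibility filters and a deterministic
# tie-break then reduce each peak to at most one formula.

#' Assignment configuration
#'
#' @param tol_ppm mass tolerance for candidate matching (ppm of the
#'   neutral mass).
#' @param ranges named list of `c(min, max)` element-count ranges for
#'   C, H, N, O, S, P. Community-standard DOM settings are the default.
#' @param hc_bounds allowed H/C ratio range.
#' @param oc_max maximum allowed O/C ratio.
#' @return An object of class `assignment_config`.
#' @details The tie-break between surviving candidates is fixed:
#'   fewest heteroatoms (N + S + P) first, then smallest absolute mass
#'   error, then canonical formula order. Heteroatom parsimony is the
#'   conventional disambiguation for DOM spectra.
#' @export
assignment_config <- function(tol_ppm = 0.5,
                              ranges = list(
                                C = c(1L, 60L), H = c(1L, 122L), N = c(0L, 4L),
                                O = c(0L, 40L), S = c(0L, 2L), P = c(0L, 1L)
                              ),
                              hc_bounds = c(0.3, 2.5),
                              oc_max = 1) {
  stopifnot(tol_ppm > 0, length(hc_bounds) == 2, hc_bounds[1] < hc_bounds[2], oc_max > 0)
  if (!all(ELEMENTS %in% names(ranges))) {
    stop("ranges must cover all of C, H, N, O, S, P", call. = FALSE)
  }
  for (el in ELEMENTS) {
    r <- ranges[[el]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) stop("invalid range for ", el, call. = FALSE)
  }
  if (ranges$C[2] < 1 || ranges$H[2] < 1) stop("ranges for C and H must allow at least 1 atom", call. = FALSE)
  structure(
    list(tol_ppm = tol_ppm, ranges = ranges, hc_bounds = hc_bounds, oc_max = oc_max),
    class = "assignment_config"
  )
}

# Precomputes the C/N/O/S/P grid (H is solved per mass) so that candidate
# search per peak is a single vectorised pass.
candidate_grid <- function(cfg, max_mass) {
  r <- cfg$ranges
  g <- expand.grid(
    C = seq.int(max(r$C[1], 1L), r$C[2]),
    N = seq.int(r$N[1], r$N[2]),
    O = seq.int(r$O[1], r$O[2]),
    S = seq.int(r$S[1], r$S[2]),
    P = seq.int(r$P[1], r$P[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  base <- g$C * ELEMENT_MASS[["C"]] + g$N * ELEMENT_MASS[["N"]] +
    g$O * ELEMENT_MASS[["O"]] + g$S * ELEMENT_MASS[["S"]] + g$P * ELEMENT_MASS[["P"]]
  keep <- base + cfg$ranges$H[1] * ELEMENT_MASS[["H"]] <= max_mass + 1
  g <- g[keep, , drop = FALSE]
  g$base_mass <- base[keep]
  g
}

# Core search against a precomputed grid; returns candidates sorted by
# |error| then canonical order.
enumerate_on_grid <- function(mass, grid, cfg) {
  h <- round((mass - grid$base_mass) / ELEMENT_MASS[["H"]])
  ok <- h >= cfg$ranges$H[1] & h <= cfg$ranges$H[2]
  if (!any(ok)) {
    return(empty_candidates())
  }
  cand_mass <- grid$base_mass[ok] + h[ok] * ELEMENT_MASS[["H"]]
  err_ppm <- (cand_mass - mass) / mass * 1e6
  hit <- abs(err_ppm) <= cfg$tol_ppm
  if (!any(hit)) {
    return(empty_candidates())
  }
  out <- data.frame(
    C = grid$C[ok][hit], H = as.integer(h[ok][hit]), N = grid$N[ok][hit],
    O = grid$O[ok][hit], S = grid$S[ok][hit], P = grid$P[ok][hit],
    mass = cand_mass[hit], error_ppm = err_ppm[hit]
  )
  out$formula <- formula_string(out)
  out[order(abs(out$error_ppm), out$formula), , drop = FALSE]
}

# Cache of fully enumerated, chemically filtered candidate spaces, keyed by
# configuration. Assigning whole surveys hits the same space repeatedly, so
# the table (sorted by mass) is built once and candidate lookup per peak
# becomes a binary search.
.space_cache <- new.env(parent = emptyenv())

space_key <- function(cfg, max_mass) {
  paste(
    cfg$tol_ppm, paste(unlist(cfg$ranges), collapse = ","),
    paste(cfg$hc_bounds, collapse = ","), cfg$oc_max, ceiling(max_mass / 100),
    sep = "|"
  )
}

filtered_candidate_space <- function(cfg, max_mass) {
  key <- space_key(cfg, max_mass)
  if (!is.null(.space_cache[[key]])) {
    return(.space_cache[[key]])
  }
  grid <- candidate_grid(cfg, max_mass)
  r <- cfg$ranges
  h_lo <- max(r$H[1], 1L)
  blocks <- lapply(seq(h_lo, r$H[2]), function(h) {
    hc <- h / grid$C
    keep <- hc >= cfg$hc_bounds[1] & hc <= cfg$hc_bounds[2] &
      (h + grid$N + grid$P) %% 2 == 0
    if (!any(keep)) {
      return(NULL)
    }
    g <- grid[keep, , drop = FALSE]
    cbind(g[c("C", "N", "O", "S", "P")],
      H = h,
      mass = g$base_mass + h * ELEMENT_MASS[["H"]]
    )
  })
  space <- do.call(rbind, blocks)
  space <- space[space$mass <= max_mass + 1, , drop = FALSE]
  d <- dbe(space)
  oc <- space$O / space$C
  keep <- d >= 0 & oc <= cfg$oc_max & space$O >= 4 * space$P &
    d - space$O <= 10
  space <- space[keep, , drop = FALSE]
  space <- space[order(space$mass), , drop = FALSE]
  space$formula <- formula_string(space)
  rownames(space) <- NULL
  .space_cache[[key]] <- space
  space
}

empty_candidates <- function() {
  data.frame(
    C = integer(), H = integer(), N = integer(), O = integer(),
    S = integer(), P = integer(), mass = numeric(), error_ppm = numeric(),
    formula = character()
  )
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Exhaustive search over the configured element ranges for formulas whose
#' monoisotopic mass lies within `cfg$tol_ppm` of `mass`, before any
#' chemical plausibility filtering.
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param cfg an [assignment_config()].
#' @return Data frame of candidates (element counts, `mass`, `error_ppm`,
#'   `formula`), ordered by absolute error then canonical form. May be
#'   empty.
#' @export
enumerate_candidates <- function(mass, cfg = assignment_config()) {
  stopifnot(is.numeric(mass), length(mass) == 1, mass > 0)
  enumerate_on_grid(mass, candidate_grid(cfg, mass), cfg)
}

#' Chemical plausibility filters
#'
#' Retains candidates that describe plausible even-electron neutral DOM
#' molecules: integer DBE >= 0, H/C within `cfg$hc_bounds`, O/C at most
#' `cfg$oc_max`, phosphorus only as phosphate (O >= 4P), and
#' DBE - O <= 10 (natural SPE-DOM carries enough oxygen to account for
#' its unsaturation; the rule suppresses near-isobaric P- and
#' hydrogen-poor false candidates).
#'
#' @param cands candidate data frame from [enumerate_candidates()].
#' @param cfg an [assignment_config()].
#' @return The filtered candidate data frame.
#' @export
apply_chemical_filters <- function(cands, cfg = assignment_config()) {
  if (nrow(cands) == 0) {
    return(cands)
  }
  d <- dbe(cands)
  hc <- cands$H / cands$C
  oc <- cands$O / cands$C
  keep <- abs(d - round(d)) < 1e-9 & d >= 0 &
    hc >= cfg$hc_bounds[1] & hc <= cfg$hc_bounds[2] &
    oc <= cfg$oc_max &
    cands$O >= 4 * cands$P &
    d - cands$O <= 10
  cands[keep, , drop = FALSE]
}

#' Assign molecular formulas to a peak list
#'
#' For every peak, the measured m/z is converted to a neutral mass
#' (singly charged [M-H]- assumed), candidates are enumerated within the
#' ppm tolerance, chemically filtered, and reduced to at most one formula
#' by the tie-break (fewest N+S+P, then smallest |error|, then canonical
#' order). Peaks with no surviving candidate are reported as unassigned.
#'
#' @param peaks a [peaklist()].
#' @param cfg an [assignment_config()].
#' @param verbose print an assignment summary to standard error.
#' @return An object of class `assigned_sample`: list with `sample_id`,
#'   `assignments` (data frame: `mz`, `intensity`, `formula`, element
#'   counts, `error_ppm`) and `unassigned` (data frame: `mz`, `intensity`).
#' @export
assign_sample <- function(peaks, cfg = assignment_config(), verbose = FALSE) {
  stopifnot(inherits(peaks, "peaklist"))
  mz <- peaks$peaks$mz
  masses <- neutral_mass(mz)
  space <- filtered_candidate_space(cfg, max(masses))
  lo <- findInterval(masses * (1 - cfg$tol_ppm * 1e-6), space$mass) + 1L
  hi <- findInterval(masses * (1 + cfg$tol_ppm * 1e-6), space$mass)
  chosen <- vector("list", length(masses))
  for (i in seq_along(masses)) {
    if (hi[i] < lo[i]) next
    cand <- space[lo[i]:hi[i], , drop = FALSE]
    cand$error_ppm <- (cand$mass - masses[i]) / masses[i] * 1e6
    het <- cand$N + cand$S + cand$P
    # P-free candidates take precedence: P-containing DOM formulas are rare
    # and conventionally require isotopologue confirmation, and several
    # near-isobaric element swaps (-N4 -O6 +C10 +H +P, 0.197 mDa) would
    # otherwise displace genuine N-rich formulas at higher mass
    cand <- cand[order(cand$P > 0, het, abs(cand$error_ppm), cand$formula), , drop = FALSE]
    chosen[[i]] <- cand[1, , drop = FALSE]
  }
  hit <- !vapply(chosen, is.null, logical(1))
  assignments <- if (any(hit)) {
    cbind(
      data.frame(mz = mz[hit], intensity = peaks$peaks$intensity[hit]),
      do.call(rbind, chosen[hit])[c("formula", ELEMENTS, "error_ppm")]
    )
  } else {
    cbind(
      data.frame(mz = numeric(), intensity = numeric()),
      empty_candidates()[c("formula", ELEMENTS, "error_ppm")]
    )
  }
  rownames(assignments) <- NULL
  if (verbose) {
    message(sprintf(
      "%s: %d/%d peaks assigned (median |error| %.3f ppm)",
      peaks$sample_id, sum(hit), length(mz),
      if (any(hit)) stats::median(abs(assignments$error_ppm)) else NA_real_
    ))
  }
  structure(
    list(
      sample_id = peaks$sample_id,
      assignments = assignments,
      unassigned = data.frame(
        mz = mz[!hit],
        intensity = peaks$peaks$intensity[!hit]
      )
    ),
    class = "assigned_sample"
  )
}

#' @export
print.assigned_sample <- function(x, ...) {
  cat(sprintf(
    "Assigned sample '%s': %d assigned, %d unassigned peaks\n",
    x$sample_id, nrow(x$assignments), nrow(x$unassigned)
  ))
  invisible(x)
}

#' Write an assignment table to CSV
#'
#' @param x an `assigned_sample`.
#' @param path output file.
#' @export
write_assignments <- function(x, path) {
  stopifnot(inherits(x, "assigned_sample"))
  utils::write.csv(
    x$assignments[c("mz", "formula", "error_ppm", "intensity")],
    path,
    row.names = FALSE
  )
}
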