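# Molecular alpha-diversity (richness, Gini-Simpson, Rao quadratic
# entropy) and beta-diversity (Jensen-Shannon divergence of binned DBE_AI
# distributions; Bray-Curtis dissimilarity of normalised intensities).

#' Molecular richness of a sample
#'
#' The number of distinct molecular formulas detected with non-zero
#' intensity (D_R).
#'
#' @param sample an `assigned_sample`, or a numeric intensity vector named
#'   by formula.
#' @return Integer count.
#' @export
richness <- function(sample) {
  ints <- sample_intensity_by_formula(sample)
  n <- sum(ints > 0)
  if (n == 0) warning("sample contains no formulas; richness 0")
  n
}

#' Gini-Simpson diversity (D_A)
#'
#' `1 - sum(p_i^2)` over relative peak intensities: the probability that
#' the molecular formulas of two randomly drawn molecules differ. Ranges
#' between 0 (one formula) and 1 - 1/n (n equally abundant formulas).
#'
#' @param p relative intensities, summing to 1.
#' @return Value in [0, 1].
#' @export
gini_simpson <- function(p) {
  check_probabilities(p)
  1 - sum(p^2)
}

check_probabilities <- function(p, tol = 1e-6) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop("input must be normalised to sum 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  invisible(p)
}

#' Functional molecular diversity (Rao quadratic entropy, D_F)
#'
#' `sum_i sum_j p_i p_j |x_i - x_j|`: the expected absolute difference in
#' a chemical property `x` between two molecules drawn according to the
#' relative intensities `p`. Computed in O(n log n) via sorting and prefix
#' sums; identical to the naive double sum.
#'
#' @param p relative intensities, summing to 1.
#' @param x per-formula property values (same length as `p`), e.g. carbon
#'   number, H/C, N/C, AI_mod, DBE or NOSC.
#' @return Non-negative value in the units of `x`.
#' @export
functional_diversity <- function(p, x) {
  check_probabilities(p)
  if (length(p) != length(x)) stop("p and x must have the same length", call. = FALSE)
  if (any(!is.finite(x))) stop("property values must be finite", call. = FALSE)
  o <- order(x)
  xs <- x[o]
  ps <- p[o]
  cp <- cumsum(ps)
  cpx <- cumsum(ps * xs)
  n <- length(xs)
  if (n < 2) {
    return(0)
  }
  # sum over ordered pairs i<j of p_i p_j (x_j - x_i), doubled
  j <- 2:n
  2 * sum(ps[j] * (xs[j] * cp[j - 1] - cpx[j - 1]))
}

#' Alpha-diversity table for a set of samples
#'
#' Computes D_R, D_A, and Rao functional diversity D_F for the six default
#' chemical properties (carbon number, H/C, N/C, AI_mod, DBE, NOSC) for
#' every sample.
#'
#' @param samples list of `assigned_sample` objects.
#' @return Data frame with one row per sample and columns `sample_id`,
#'   `D_R`, `D_A`, `D_F_C`, `D_F_HC`, `D_F_NC`, `D_F_AImod`, `D_F_DBE`,
#'   `D_F_NOSC`.
#' @export
alpha_diversity <- function(samples) {
  rows <- lapply(samples, function(s) {
    ints <- sample_intensity_by_formula(s)
    p <- as.vector(ints) / sum(ints)
    f <- parse_formula(names(ints))
    data.frame(
      sample_id = s$sample_id,
      D_R = sum(ints > 0),
      D_A = gini_simpson(p),
      D_F_C = functional_diversity(p, f$C),
      D_F_HC = functional_diversity(p, f$H / f$C),
      D_F_NC = functional_diversity(p, f$N / f$C),
      D_F_AImod = functional_diversity(p, ai_mod(f)),
      D_F_DBE = functional_diversity(p, dbe(f)),
      D_F_NOSC = functional_diversity(p, nosc(f))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned index distribution of a sample
#'
#' The empirical distribution of a per-formula index (DBE_AI by default)
#' over a sample's distinct formulas, binned on the global 0.5 grid.
#' Presence-based: each distinct formula counts once, so the distribution
#' ignores peak intensities. An intensity-weighted variant is available
#' but off by default.
#'
#' @param sample an `assigned_sample` or named intensity vector.
#' @param index which per-formula index to bin (`"dbe_ai"` or `"dbe"`).
#' @param bin_width bin width; DBE_AI is naturally binned in 0.5 steps.
#' @param weighted if `TRUE`, bins carry summed relative intensity rather
#'   than formula counts.
#' @return Object of class `binned_distribution`: list with `bin_centers`
#'   (ascending, on the grid) and `probabilities` (summing to 1).
#' @export
binned_distribution <- function(sample, index = c("dbe_ai", "dbe"),
                                bin_width = 0.5, weighted = FALSE) {
  index <- match.arg(index)
  ints <- sample_intensity_by_formula(sample)
  ints <- ints[ints > 0]
  if (length(ints) == 0) stop("empty sample: no formulas to bin", call. = FALSE)
  f <- parse_formula(names(ints))
  x <- switch(index, dbe_ai = dbe_ai(f), dbe = dbe(f))
  centers <- round(x / bin_width) * bin_width
  w <- if (weighted) as.vector(ints) / sum(ints) else rep(1 / length(x), length(x))
  p <- tapply(w, centers, sum)
  structure(
    list(
      bin_centers = as.numeric(names(p)),
      probabilities = as.vector(p)
    ),
    class = "binned_distribution"
  )
}

#' Jensen-Shannon divergence of two binned distributions
#'
#' `JSd(P, Q) = 0.5 KL(P || M) + 0.5 KL(Q || M)` with `M = (P + Q) / 2`,
#' using base-2 logarithms so the divergence is bound between 0 (identical
#' distributions) and 1 (disjoint supports). Bins are aligned on the union
#' of the two supports; empty bins contribute nothing (0 log 0 = 0).
#'
#' @param pd,qd `binned_distribution` objects, or plain numeric probability
#'   vectors already on a common grid.
#' @return Value in [0, 1]; symmetric in its arguments.
#' @export
jensen_shannon <- function(pd, qd) {
  if (inherits(pd, "binned_distribution") && inherits(qd, "binned_distribution")) {
    grid <- sort(unique(c(pd$bin_centers, qd$bin_centers)))
    p <- q <- numeric(length(grid))
    p[match(pd$bin_centers, grid)] <- pd$probabilities
    q[match(qd$bin_centers, grid)] <- qd$probabilities
  } else {
    p <- as.numeric(pd)
    q <- as.numeric(qd)
    if (length(p) != length(q)) stop("probability vectors must share a grid", call. = FALSE)
  }
  check_probabilities(p)
  check_probabilities(q)
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  val <- 0.5 * kl(p) + 0.5 * kl(q)
  min(max(val, 0), 1)
}

#' Jensen-Shannon divergence matrix of samples
#'
#' Pairwise JSd between the binned index distributions (DBE_AI by default)
#' of all samples; the package's primary molecular beta-diversity.
#'
#' @param samples list of `assigned_sample` objects (>= 2, unique ids).
#' @inheritParams binned_distribution
#' @return A `dist` object with sample labels; entries in [0, 1].
#' @export
jsd_matrix <- function(samples, index = "dbe_ai", bin_width = 0.5,
                       weighted = FALSE) {
  stopifnot(length(samples) >= 2)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id", call. = FALSE)
  dists <- lapply(samples, binned_distribution,
    index = index, bin_width = bin_width, weighted = weighted
  )
  n <- length(samples)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jensen_shannon(dists[[i]], dists[[j]])
    }
  }
  stats::as.dist(m)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over normalised peak
#' intensities; computed with [vegan::vegdist()].
#'
#' @param m row-normalised sample x formula matrix.
#' @return A `dist` object; entries in [0, 1].
#' @export
bray_curtis_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (any(rowSums(m) == 0)) {
    stop("zero-intensity sample: ", rownames(m)[rowSums(m) == 0][1], call. = FALSE)
  }
  vegan::vegdist(m, method = "bray")
}

#' Write a distance matrix as square CSV
#'
#' @param d a `dist` object with labels.
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(as.matrix(d)), path, row.names = TRUE)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("matrix in ", path, " is not symmetric", call. = FALSE)
  }
  stats::as.dist(m)
}
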