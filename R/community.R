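# Clustering, ordination, indicator-formula analysis and distance-decay
# tests on the distance matrices and the environment table.

#' Average-linkage clustering with silhouette-based choice of k
#'
#' Builds an average-linkage dendrogram from the distance matrix, cuts it
#' at every k in `k_range`, and keeps the partition maximising the mean
#' silhouette width computed from the original distances (not from any
#' ordination). Ties are broken towards the smallest k.
#'
#' @param d a `dist` object with sample labels.
#' @param k_range candidate numbers of clusters; must lie in [2, n - 1].
#' @return Object of class `cluster_assignment`: list with `labels`
#'   (named integer vector 1..k), `k`, `mean_silhouette`, `silhouette`
#'   (per-sample widths), `hclust` (the dendrogram) and
#'   `silhouette_by_k`.
#' @export
hierarchical_cluster <- function(d, k_range = 2:10) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 4) stop("need at least 4 samples to cluster", call. = FALSE)
  if (missing(k_range)) k_range <- 2:min(10, n - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  hc <- stats::hclust(d, method = "average")
  sil_by_k <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  if (max(sil_by_k) - min(sil_by_k) < 1e-12 && length(k_range) > 1) {
    warning("silhouette is flat across k_range; choosing the smallest k")
  }
  best <- k_range[which.max(sil_by_k)] # which.max takes the first maximum
  labels <- stats::cutree(hc, k = best)
  sil <- cluster::silhouette(labels, d)
  structure(
    list(
      labels = labels,
      k = best,
      mean_silhouette = mean(sil[, "sil_width"]),
      silhouette = stats::setNames(sil[, "sil_width"], names(labels)),
      hclust = hc,
      silhouette_by_k = stats::setNames(sil_by_k, k_range)
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "Average-linkage clustering: k = %d (mean silhouette %.3f)\n",
    x$k, x$mean_silhouette
  ))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Write a dendrogram in Newick format
#'
#' @param x a `cluster_assignment` or `hclust` object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(x, path) {
  hc <- if (inherits(x, "cluster_assignment")) x$hclust else x
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Rank-based ordination minimising stress over random restarts, via
#' [vegan::metaMDS()]. Reproducible given `seed`.
#'
#' @param d a `dist` object.
#' @param dims number of ordination axes.
#' @param n_starts maximum number of random starts.
#' @param seed integer seed for the random starts.
#' @return Object of class `nmds_ordination`: list with `points`
#'   (n x dims coordinates), `stress`, `converged` and the underlying
#'   `metaMDS` object.
#' @export
nmds_ordination <- function(d, dims = 2, n_starts = 20, seed = 1) {
  stopifnot(inherits(d, "dist"))
  set.seed(seed)
  fit <- vegan::metaMDS(d,
    k = dims, trymax = n_starts, trace = 0,
    autotransform = FALSE, wascores = FALSE
  )
  if (!is.finite(fit$stress)) {
    stop("NMDS did not produce a finite stress in any start", call. = FALSE)
  }
  structure(
    list(
      points = fit$points,
      stress = fit$stress,
      converged = isTRUE(fit$converged) || fit$stress < 1e-3,
      fit = fit
    ),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf(
    "NMDS ordination: %d samples, %d axes, stress %.4f\n",
    nrow(x$points), ncol(x$points), x$stress
  ))
  invisible(x)
}

#' Post-hoc fitting of environmental variables to an ordination
#'
#' Least-squares vector fitting of each variable onto the ordination axes
#' (via [vegan::envfit()]); significance by permutation of the variable.
#'
#' @param ordination an `nmds_ordination`.
#' @param env environment table (rows in ordination sample order).
#' @param vars variables to fit; must be complete and non-constant.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Data frame with one row per variable: direction cosines on the
#'   axes, `r2`, and permutation `p`.
#' @export
fit_env_vectors <- function(ordination, env, vars, n_perm = 9999, seed = 1) {
  stopifnot(inherits(ordination, "nmds_ordination"))
  miss <- setdiff(vars, names(env))
  if (length(miss)) stop("variables absent from env: ", paste(miss, collapse = ", "), call. = FALSE)
  x <- env[vars]
  if (anyNA(x)) stop("missing values among fitted variables", call. = FALSE)
  const <- vars[vapply(x, function(v) stats::var(as.numeric(v)) == 0, logical(1))]
  if (length(const)) stop("constant variable: ", paste(const, collapse = ", "), call. = FALSE)
  set.seed(seed)
  ef <- vegan::envfit(ordination$points, x, permutations = n_perm)
  arrows <- ef$vectors$arrows
  colnames(arrows) <- paste0("axis", seq_len(ncol(arrows)))
  data.frame(
    variable = rownames(arrows),
    arrows,
    r2 = ef$vectors$r,
    p = ef$vectors$pvals,
    row.names = NULL
  )
}

#' Indicator-formula (IndVal) analysis
#'
#' For every formula and cluster: specificity `A` (mean abundance in the
#' cluster divided by the summed cluster means, group-size-unweighted) and
#' fidelity `B` (fraction of the cluster's samples containing the
#' formula). The indicator value is `max_c A_c * B_c`; it reaches 1 when a
#' formula occurs in every sample of exactly one cluster and nowhere else.
#' Significance by permuting cluster labels; p-values are
#' `(1 + #{perm >= observed}) / (n_perm + 1)` and Benjamini-Hochberg
#' adjusted across formulas.
#'
#' @param m normalised sample x formula matrix.
#' @param clusters `cluster_assignment`, or a vector of cluster labels
#'   named by sample (every cluster needs >= 2 samples).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param alpha adjusted-p significance threshold.
#' @return Data frame with one row per formula: `formula`, `best_cluster`,
#'   `A`, `B`, `indval`, `p_raw`, `p_adjusted`, `significant`.
#' @export
indval <- function(m, clusters, n_perm = 9999, seed = 1, alpha = 0.05) {
  stopifnot(is.matrix(m))
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels else clusters
  if (!is.null(names(labels)) && !is.null(rownames(m))) {
    if (!setequal(names(labels), rownames(m))) {
      stop("cluster labels and matrix rows name different samples", call. = FALSE)
    }
    labels <- labels[rownames(m)]
  }
  if (length(labels) != nrow(m)) stop("one cluster label per sample required", call. = FALSE)
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  if (length(sizes) < 2) stop("need at least 2 clusters", call. = FALSE)
  if (any(sizes < 2)) stop("singleton cluster: every cluster needs >= 2 samples", call. = FALSE)
  pres <- (m > 0) * 1

  stat_all <- function(lab) {
    grp_mean <- rowsum(m, lab) / sizes # k x p mean abundance
    grp_freq <- rowsum(pres, lab) / sizes # k x p occurrence fraction
    tot <- colSums(grp_mean)
    A <- sweep(grp_mean, 2, pmax(tot, .Machine$double.xmin), "/")
    A[, tot == 0] <- 0
    iv <- A * grp_freq
    list(iv = iv, best = apply(iv, 2, which.max), stat = apply(iv, 2, max))
  }

  obs <- stat_all(labels)
  set.seed(seed)
  exceed <- numeric(ncol(m))
  for (b in seq_len(n_perm)) {
    perm <- stat_all(sample(labels))
    exceed <- exceed + (perm$stat >= obs$stat - 1e-12)
  }
  p_raw <- (1 + exceed) / (n_perm + 1)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  comp <- indval_components(m, pres, labels, sizes, obs$best)
  data.frame(
    formula = colnames(m),
    best_cluster = obs$best,
    A = comp$A,
    B = comp$B,
    indval = obs$stat,
    p_raw = p_raw,
    p_adjusted = p_adj,
    significant = p_adj <= alpha,
    row.names = NULL
  )
}

indval_components <- function(m, pres, labels, sizes, best) {
  grp_mean <- rowsum(m, labels) / sizes
  grp_freq <- rowsum(pres, labels) / sizes
  tot <- colSums(grp_mean)
  A <- grp_mean[cbind(best, seq_len(ncol(m)))] / ifelse(tot == 0, 1, tot)
  A[tot == 0] <- 0
  B <- grp_freq[cbind(best, seq_len(ncol(m)))]
  list(A = A, B = B)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r_M` between corresponding lower-triangle entries,
#' with a one-sided (greater) permutation test obtained by jointly
#' permuting rows and columns of one matrix (via [vegan::mantel()]);
#' `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param d1,d2 `dist` objects over the same samples in the same order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `r` (the Mantel statistic), `p` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1) {
  stopifnot(inherits(d1, "dist"), inherits(d2, "dist"))
  l1 <- attr(d1, "Labels")
  l2 <- attr(d2, "Labels")
  if (attr(d1, "Size") != attr(d2, "Size")) stop("distance matrices differ in size", call. = FALSE)
  if (!is.null(l1) && !is.null(l2) && !all(as.character(l1) == as.character(l2))) {
    stop("distance matrices name different samples (or a different order)", call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Great-circle distance matrix between lakes
#'
#' Haversine distances on a sphere of radius 6371.0088 km.
#'
#' @param env environment table with `latitude`, `longitude` (degrees) and
#'   `lake_id`, or a data frame with just those columns.
#' @return A `dist` object in kilometres, labelled by `lake_id` when
#'   available.
#' @export
haversine_matrix <- function(env) {
  if (any(env$latitude < -90 | env$latitude > 90) ||
    any(env$longitude < -180 | env$longitude > 180)) {
    stop("coordinates out of range", call. = FALSE)
  }
  xy <- cbind(env$longitude, env$latitude)
  m <- geosphere::distm(xy, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371.0088)
  })
  ids <- if (!is.null(env$lake_id)) env$lake_id else rownames(env)
  dimnames(m) <- list(ids, ids)
  stats::as.dist(m)
}

#' Environmental distance matrix
#'
#' Each selected variable is optionally transformed, z-scored across
#' samples, and the samples' Euclidean distances are returned. EC is
#' log10-transformed by default because conductivity spans orders of
#' magnitude across lake types.
#'
#' @param env environment table.
#' @param vars variables entering the distance (default: EC, pH,
#'   water_temperature, DIN).
#' @param transforms named character vector mapping variables to
#'   transforms (`"log10"` or `"identity"`).
#' @return A `dist` object labelled by `lake_id` when available.
#' @export
env_distance <- function(env,
                         vars = c("EC", "pH", "water_temperature", "DIN"),
                         transforms = c(EC = "log10")) {
  miss <- setdiff(vars, names(env))
  if (length(miss)) stop("variables absent from env: ", paste(miss, collapse = ", "), call. = FALSE)
  x <- as.data.frame(env[vars])
  if (anyNA(x)) stop("missing values among selected variables", call. = FALSE)
  for (v in intersect(names(transforms), vars)) {
    x[[v]] <- switch(transforms[[v]],
      log10 = {
        if (any(x[[v]] <= 0)) stop("log10 transform needs positive ", v, call. = FALSE)
        log10(x[[v]])
      },
      identity = x[[v]],
      stop("unknown transform: ", transforms[[v]], call. = FALSE)
    )
  }
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("zero-variance variable: ", vars[sds == 0][1], call. = FALSE)
  }
  z <- scale(as.matrix(x))
  rownames(z) <- if (!is.null(env$lake_id)) env$lake_id else rownames(env)
  stats::dist(z)
}
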