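# Peak-list and metadata I/O, blank filtering, and assembly of the
# sample x formula intensity matrix.

#' Construct a peak list
#'
#' @param mz measured mass-to-charge ratios (Da), negative mode.
#' @param intensity peak intensities (arbitrary units, > 0).
#' @param sample_id sample identifier.
#' @return Object of class `peaklist`: list with `sample_id`, `charge_mode`
#'   and a data frame `peaks` sorted by ascending `mz`.
#' @details Invariants enforced: all m/z strictly positive, intensities
#'   strictly positive, and no two peaks within 0.1 mDa of each other
#'   (duplicates are rejected, not merged).
#' @export
peaklist <- function(mz, intensity, sample_id = "sample") {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ", call. = FALSE)
  if (length(mz) == 0) stop("empty peak list", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("m/z values must be positive and finite", call. = FALSE)
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad)) {
    stop("non-positive intensity at row ", bad[1], " (mz = ", mz[bad[1]], ")", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (any(diff(mz) < 1e-4)) {
    i <- which(diff(mz) < 1e-4)[1]
    stop(
      "duplicate m/z within 0.1 mDa: ", mz[i], " and ", mz[i + 1],
      call. = FALSE
    )
  }
  structure(
    list(
      sample_id = sample_id,
      charge_mode = "negative",
      peaks = data.frame(mz = mz, intensity = intensity)
    ),
    class = "peaklist"
  )
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf(
    "Peak list '%s': %d peaks, m/z %.4f-%.4f\n",
    x$sample_id, nrow(x$peaks), min(x$peaks$mz), max(x$peaks$mz)
  ))
  invisible(x)
}

#' Read a calibrated peak list from delimited text
#'
#' @param path file with columns for m/z and intensity.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @param header logical; does the file carry a header line with columns
#'   `mz` and `intensity`? Without a header the first two columns are used.
#' @param mass_window valid m/z window in Da; peaks outside are dropped
#'   with a message. The lower bound matches the instrument scan range;
#'   DOM signals concentrate below 1000 Da.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, sample_id = NULL, sep = ",", header = TRUE,
                          mass_window = c(92, 1000)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = header, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(tab) == 0) stop("empty peak list file: ", path, call. = FALSE)
  if (header) {
    if (!all(c("mz", "intensity") %in% names(tab))) {
      stop(path, ": header must provide columns 'mz' and 'intensity'", call. = FALSE)
    }
    mz <- tab$mz
    intensity <- tab$intensity
  } else {
    mz <- tab[[1]]
    intensity <- tab[[2]]
  }
  if (!is.numeric(mz) || !is.numeric(intensity) || anyNA(mz) || anyNA(intensity)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(mz))) |
      !is.finite(suppressWarnings(as.numeric(intensity))))[1]
    stop(path, ": unparseable numeric value at data row ", bad, call. = FALSE)
  }
  inside <- mz >= mass_window[1] & mz <= mass_window[2]
  if (any(!inside)) {
    message(sum(!inside), " peaks outside mass window [",
      mass_window[1], ", ", mass_window[2], "] Da dropped")
  }
  if (!any(inside)) stop(path, ": no peaks inside the mass window", call. = FALSE)
  peaklist(mz[inside], intensity[inside], sample_id = sample_id)
}

#' Write a peak list as CSV
#'
#' @param x a [peaklist()].
#' @param path output file.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  utils::write.csv(x$peaks, path, row.names = FALSE)
}

#' Subtract a process blank from a sample peak list
#'
#' Sample peaks matched to a blank peak within `mz_tol` ppm are retained
#' only when the sample intensity is at least `ratio_min` times the blank
#' intensity; conventional detection-limit practice for process blanks.
#'
#' @param sample,blank [peaklist()] objects.
#' @param mz_tol match tolerance in ppm.
#' @param ratio_min minimum sample/blank intensity ratio (> 1).
#' @return The filtered [peaklist()], with the removed peaks attached as
#'   attribute `"removed"` (data frame: `mz`, `intensity`, `blank_mz`,
#'   `blank_intensity`).
#' @export
blank_filter <- function(sample, blank, mz_tol = 0.5, ratio_min = 5) {
  stopifnot(inherits(sample, "peaklist"), inherits(blank, "peaklist"))
  if (ratio_min <= 1) stop("ratio_min must exceed 1", call. = FALSE)
  smz <- sample$peaks$mz
  bmz <- blank$peaks$mz
  # nearest blank peak for each sample peak
  idx <- findInterval(smz, bmz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(bmz))
  d_lo <- abs(smz - bmz[lo])
  d_hi <- abs(smz - bmz[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  matched <- abs(smz - bmz[nearest]) / smz * 1e6 <= mz_tol
  remove <- matched &
    sample$peaks$intensity < ratio_min * blank$peaks$intensity[nearest]
  removed <- data.frame(
    mz = smz[remove],
    intensity = sample$peaks$intensity[remove],
    blank_mz = bmz[nearest][remove],
    blank_intensity = blank$peaks$intensity[nearest][remove]
  )
  if (all(remove)) stop("blank filtering removed every peak", call. = FALSE)
  out <- peaklist(smz[!remove], sample$peaks$intensity[!remove],
    sample_id = sample$sample_id
  )
  attr(out, "removed") <- removed
  out
}

#' Read a sample metadata table
#'
#' @param path CSV with one row per sample; must provide `lake_id`,
#'   `lake_type` (proglacial, freshwater, saline or hypersaline),
#'   `latitude`, `longitude`, `EC` (S/m), `pH`, `water_temperature` (deg C)
#'   and `DIN` (umol/L); further columns (DOC, optical indices, ...) are
#'   carried through.
#' @return Validated data frame.
#' @export
read_environment_table <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_environment_table(env)
}

#' @rdname read_environment_table
#' @param env data frame to validate in place of a file.
#' @export
validate_environment_table <- function(env) {
  need <- c(
    "lake_id", "lake_type", "latitude", "longitude", "EC", "pH",
    "water_temperature", "DIN"
  )
  miss <- setdiff(need, names(env))
  if (length(miss)) stop("metadata misses columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(env$lake_id)) stop("duplicate lake_id in metadata", call. = FALSE)
  types <- c("proglacial", "freshwater", "saline", "hypersaline")
  if (!all(env$lake_type %in% types)) {
    stop("lake_type must be one of: ", paste(types, collapse = ", "), call. = FALSE)
  }
  if (any(env$latitude < -90 | env$latitude > 90)) stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(env$longitude < -180 | env$longitude > 180)) stop("longitude out of [-180, 180]", call. = FALSE)
  if (any(env$EC <= 0)) stop("EC must be positive", call. = FALSE)
  env$lake_type <- factor(env$lake_type, levels = types)
  env
}

#' Assemble the sample x formula intensity matrix
#'
#' Columns are the union of assigned formulas across samples (canonical
#' strings, sorted by exact mass with element-count tie-break); a formula
#' absent from a sample gets 0; several peaks mapped to one formula within
#' a sample are summed.
#'
#' @param samples list of `assigned_sample` objects (>= 2, unique ids).
#' @return Numeric matrix with sample rows and formula columns.
#' @export
assemble_formula_matrix <- function(samples) {
  stopifnot(length(samples) >= 2)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id: ", ids[duplicated(ids)][1], call. = FALSE)
  per_sample <- lapply(samples, function(s) {
    tapply(s$assignments$intensity, s$assignments$formula, sum)
  })
  all_keys <- unique(unlist(lapply(per_sample, names)))
  f <- parse_formula(all_keys)
  all_keys <- all_keys[formula_order(f)]
  m <- matrix(0, nrow = length(samples), ncol = length(all_keys),
    dimnames = list(ids, all_keys)
  )
  for (i in seq_along(per_sample)) {
    v <- per_sample[[i]]
    m[i, names(v)] <- as.vector(v)
  }
  m
}

#' Normalise a formula matrix to relative intensities
#'
#' Peak intensities for each sample are divided by the sample's total
#' intensity, so every row sums to 1; zeros stay zero. Idempotent.
#'
#' @param m sample x formula matrix with non-negative entries.
#' @return Row-normalised matrix.
#' @export
normalize_intensities <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("zero-intensity sample: ", rownames(m)[rs == 0][1], call. = FALSE)
  }
  sweep(m, 1, rs, "/")
}

#' Replicate quality control
#'
#' Bray-Curtis dissimilarity between repeated analyses of the same
#' reference sample; replicate runs of one sample are expected to differ
#' by at most `threshold` (default 0.05).
#'
#' @param m normalised matrix whose rows are replicate analyses of one
#'   reference material.
#' @param threshold dissimilarity above which replicates are flagged.
#' @return List with the replicate `dist` object, `max_dissimilarity` and
#'   logical `flagged`.
#' @export
replicate_qc <- function(m, threshold = 0.05) {
  d <- bray_curtis_matrix(normalize_intensities(m))
  list(
    dissimilarity = d,
    max_dissimilarity = max(d),
    flagged = max(d) > threshold
  )
}

#' Write / read a formula matrix as CSV
#'
#' Sample rows, canonical formula-string columns; bit-stable for fixed
#' input.
#'
#' @param m matrix from [assemble_formula_matrix()].
#' @param path CSV file.
#' @export
write_formula_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
}

#' @rdname write_formula_matrix
#' @export
read_formula_matrix <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}
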