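#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Row-major order over the strict upper triangle: (1,2), (1,3), ..., (1,P),
#' (2,3), ... This single convention is shared by every module in the
#' package.
#'
#' @param m Square numeric matrix (P x P).
#' @return Numeric vector of length P(P-1)/2.
#' @seealso [unvectorize_fc()], [edge_names()]
#' @export
vectorize_fc <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) fail("connectivity matrix must be square")
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric connectivity matrix from its edge vector
#'
#' Inverse of [vectorize_fc()]; the diagonal is set to 1.
#'
#' @param v Edge vector of length P(P-1)/2.
#' @param n_rois Number of regions P.
#' @return Symmetric P x P matrix with unit diagonal.
#' @export
unvectorize_fc <- function(v, n_rois) {
  expected <- n_rois * (n_rois - 1L) / 2L
  if (length(v) != expected) {
    fail("edge vector has length %d, expected %d for P=%d", length(v), expected, n_rois)
  }
  m <- matrix(0, n_rois, n_rois)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Edge labels in vectorization order
#'
#' @param n_rois Number of regions P.
#' @return Character vector `ROIi_ROIj` (i < j), row-major upper triangle.
#' @export
edge_names <- function(n_rois) {
  idx <- which(lower.tri(matrix(0, n_rois, n_rois)), arr.ind = TRUE)
  paste0("ROI", idx[, 2], "_ROI", idx[, 1])
}

#' A single vectorized connectivity pattern
#'
#' @param values Edge vector, entries in \[-1, 1\], length P(P-1)/2.
#' @param subject_id,scan_id Identity tokens.
#' @param n_rois Number of regions P.
#' @param window_index 0-based window index for dynamic FC, or `NA` for
#'   full-scan (static) FC.
#' @return An object of class `fc_vector`.
#' @export
fc_vector <- function(values, subject_id, scan_id, n_rois, window_index = NA_integer_) {
  values <- as.numeric(values)
  expected <- n_rois * (n_rois - 1L) / 2L
  if (length(values) != expected) {
    fail("fc_vector has %d entries, expected %d for P=%d", length(values), expected, n_rois)
  }
  if (any(!is.finite(values)) || any(abs(values) > 1 + 1e-12)) {
    fail("fc_vector entries must be finite correlations in [-1, 1]")
  }
  structure(
    list(
      values = pmin(1, pmax(-1, values)),
      subject_id = as.character(subject_id),
      scan_id = as.character(scan_id),
      window_index = as.integer(window_index),
      n_rois = as.integer(n_rois)
    ),
    class = "fc_vector"
  )
}

# Internal fc_set constructor (no per-row validation; values already checked).
new_fc_set <- function(values, meta, n_rois) {
  rownames(values) <- NULL
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, n_rois = as.integer(n_rois)),
    class = "fc_set"
  )
}

#' Collect connectivity vectors into a cohort-level set
#'
#' An `fc_set` holds an S x E matrix of edge values plus a metadata frame
#' (`subject_id`, `scan_id`, `window_index`) aligned row-wise. Most
#' cohort-level operations (fingerprinting, splits, prediction) take one.
#'
#' @param vectors A list of [fc_vector()] objects (or a single one), all with
#'   the same `n_rois`.
#' @return An object of class `fc_set`.
#' @export
fc_set <- function(vectors) {
  if (inherits(vectors, "fc_vector")) vectors <- list(vectors)
  if (inherits(vectors, "fc_set")) {
    return(vectors)
  }
  if (length(vectors) == 0) fail("fc_set needs at least one vector")
  stopifnot(all(vapply(vectors, inherits, logical(1), "fc_vector")))
  p <- unique(vapply(vectors, `[[`, integer(1), "n_rois"))
  if (length(p) != 1L) fail("all vectors in an fc_set must share n_rois")
  values <- t(vapply(vectors, `[[`, numeric(p * (p - 1L) / 2L), "values"))
  meta <- data.frame(
    subject_id = vapply(vectors, `[[`, character(1), "subject_id"),
    scan_id = vapply(vectors, `[[`, character(1), "scan_id"),
    window_index = vapply(vectors, `[[`, integer(1), "window_index"),
    stringsAsFactors = FALSE
  )
  new_fc_set(values, meta, p)
}

#' @export
print.fc_set <- function(x, ...) {
  cat(sprintf(
    "fc_set: %d vectors x %d edges (P=%d), %d subjects\n",
    nrow(x$values), ncol(x$values), x$n_rois, length(unique(x$meta$subject_id))
  ))
  invisible(x)
}

#' Band-pass filter specification
#'
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)` (the Nyquist frequency).
#' @param tr_seconds Repetition time of the series the filter targets.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 0.01, high_hz = 0.15, tr_seconds = 2) {
  if (!is_scalar_number(tr_seconds) || tr_seconds <= 0) fail("tr_seconds must be > 0")
  nyquist <- 1 / (2 * tr_seconds)
  if (!is_scalar_number(low_hz) || low_hz <= 0) {
    fail("bandpass_spec: low_hz must be > 0")
  }
  if (!is_scalar_number(high_hz) || high_hz <= low_hz) {
    fail("bandpass_spec: high_hz must exceed low_hz")
  }
  if (high_hz >= nyquist) {
    fail("bandpass_spec: high_hz (%g) must be below the Nyquist frequency (%g)", high_hz, nyquist)
  }
  structure(
    list(low_hz = low_hz, high_hz = high_hz, tr_seconds = tr_seconds),
    class = "bandpass_spec"
  )
}

# Minimum series length for stable zero-phase filtering. The reflection pad
# grows with the series (up to 100 samples): the low-cut poles of a
# 0.01-Hz-edge band-pass settle slowly, and a short pad leaves visible edge
# transients.
bandpass_filter_order <- 4L
bandpass_min_len <- 3L * (2L * bandpass_filter_order + 1L)
bandpass_max_pad <- 100L

#' Zero-phase Butterworth band-pass filter for ROI timeseries
#'
#' Applies an order-4 Butterworth band-pass forward and backward
#' (zero phase, so no time shift) to each ROI column independently. The
#' series is extended by odd reflection at both ends before filtering and
#' trimmed afterwards, which suppresses startup transients.
#'
#' @param ts A [roi_timeseries()].
#' @param spec A [bandpass_spec()]; its `tr_seconds` must match the scan's.
#' @return A filtered [roi_timeseries()] of the same shape.
#' @export
bandpass_filter <- function(ts, spec) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(spec, "bandpass_spec"))
  if (abs(spec$tr_seconds - ts$tr_seconds) > 1e-9) {
    fail(
      "bandpass_spec tr_seconds (%g) does not match scan tr_seconds (%g)",
      spec$tr_seconds, ts$tr_seconds
    )
  }
  n <- nrow(ts$values)
  if (n <= bandpass_min_len) {
    fail("timeseries too short for stable filtering: T=%d, need T > %d", n, bandpass_min_len)
  }
  pad <- min(n - 1L, bandpass_max_pad)
  nyquist <- 1 / (2 * ts$tr_seconds)
  bf <- signal::butter(bandpass_filter_order,
    W = c(spec$low_hz, spec$high_hz) / nyquist, type = "pass"
  )
  filtered <- apply(ts$values, 2, function(x) {
    # odd reflection padding at both ends, as in standard filtfilt practice
    head_pad <- 2 * x[1] - x[(pad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(pad + 1):(pad + n)]
  })
  colnames(filtered) <- colnames(ts$values)
  roi_timeseries(filtered, ts$subject_id, ts$scan_id, ts$tr_seconds)
}

# Pearson FC on a raw matrix; shared by static and windowed paths.
fc_from_matrix <- function(x, subject_id, scan_id, window_index = NA_integer_) {
  if (nrow(x) < 3L) fail("need at least 3 timepoints to estimate correlations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    fail(
      "zero-variance ROI column(s): %s",
      paste(colnames(x)[sds == 0], collapse = ", ")
    )
  }
  r <- stats::cor(x)
  fc_vector(vectorize_fc(r),
    subject_id = subject_id, scan_id = scan_id,
    n_rois = ncol(x), window_index = window_index
  )
}

#' Static functional connectivity of one scan
#'
#' Pearson correlation between every pair of ROI timeseries, reduced to the
#' strict upper triangle and vectorized (row-major; see [vectorize_fc()]).
#'
#' @param ts A [roi_timeseries()] (typically band-pass filtered first).
#' @return An [fc_vector()] with `window_index = NA`.
#' @export
compute_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  fc_from_matrix(ts$values, ts$subject_id, ts$scan_id)
}

#' Dynamic functional connectivity over non-overlapping windows
#'
#' Splits the scan into consecutive non-overlapping windows of
#' `window_trs` timepoints anchored at the first TR (0-based half-open
#' intervals \[0, w), \[w, 2w), ...), discards any trailing partial window,
#' and computes Pearson FC within each window. Filtering, when used, is
#' applied to the full series before windowing: filtering short windows
#' independently is numerically fragile.
#'
#' @param ts A [roi_timeseries()].
#' @param window_trs Window length in TRs (default 50).
#' @return A list of [fc_vector()] with `window_index` 0, 1, ...;
#'   length `floor(T / window_trs)`.
#' @export
compute_dfc <- function(ts, window_trs = 50L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (!is_count(window_trs, min = 3L)) fail("window_trs must be an integer >= 3")
  n <- nrow(ts$values)
  if (n < window_trs) {
    fail("scan has T=%d timepoints, fewer than one window of %d TRs", n, window_trs)
  }
  n_windows <- n %/% window_trs
  lapply(seq_len(n_windows) - 1L, function(w) {
    rows <- (w * window_trs + 1L):((w + 1L) * window_trs)
    fc_from_matrix(ts$values[rows, , drop = FALSE],
      ts$subject_id, ts$scan_id,
      window_index = w
    )
  })
}

#' Cohort-level connectivity: filter + FC/dFC over every scan
#'
#' Convenience wrapper applying an optional band-pass filter and then either
#' static FC (one vector per scan) or windowed dFC (several per scan) across
#' a whole cohort.
#'
#' @param scans List of [roi_timeseries()].
#' @param bandpass A [bandpass_spec()], or `NULL` to skip filtering.
#' @param window_trs Window length in TRs for dFC, or `NULL` for static FC.
#' @return An [fc_set()].
#' @export
cohort_fc <- function(scans, bandpass = NULL, window_trs = NULL) {
  vectors <- list()
  for (ts in scans) {
    if (!is.null(bandpass)) ts <- bandpass_filter(ts, bandpass)
    if (is.null(window_trs)) {
      vectors[[length(vectors) + 1L]] <- compute_fc(ts)
    } else {
      vectors <- c(vectors, compute_dfc(ts, window_trs))
    }
  }
  fc_set(vectors)
}

#' Write an fc_set as a single CSV
#'
#' One row per vector: `subject_id`, `scan_id`, `window_index`, then one
#' column per edge named `ROIi_ROIj` in vectorization order.
#'
#' @param fc An [fc_set()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_fc_csv <- function(fc, path) {
  df <- cbind(fc$meta, as.data.frame(fc$values))
  names(df)[-(1:3)] <- edge_names(fc$n_rois)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an fc_set from a CSV written by [write_fc_csv()]
#'
#' @param path CSV path.
#' @return An [fc_set()].
#' @export
read_fc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_edges <- ncol(df) - 3L
  p <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (p != round(p)) fail("edge column count %d is not P(P-1)/2 for integer P", n_edges)
  new_fc_set(
    values = as.matrix(df[, -(1:3), drop = FALSE]),
    meta = data.frame(
      subject_id = as.character(df$subject_id),
      scan_id = as.character(df$scan_id),
      window_index = as.integer(df$window_index),
      stringsAsFactors = FALSE
    ),
    n_rois = as.integer(round(p))
  )
}
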