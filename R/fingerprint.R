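#' Cosine similarity between two connectivity vectors
#'
#' \eqn{sim(a, b) = a^T b / (\|a\|_2 \|b\|_2)}, the similarity used for
#' subject identification. Invariant to positive rescaling of either
#' argument; flips sign under negative rescaling.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    fail("cosine_similarity: length mismatch (%d vs %d)", length(a), length(b))
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) fail("cosine_similarity is undefined for a zero vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Pairwise similarity matrix over a cohort of connectivity vectors
#'
#' For `metric = "cosine"`: symmetric with unit diagonal, entries in
#' \[-1, 1\]. For `metric = "euclidean"`: the negated Euclidean distance, so
#' that "higher = more similar" holds uniformly; the diagonal is then 0 and
#' the unit-diagonal property is waived (recorded in the `metric` field).
#'
#' @param fc An [fc_set()] (or list of [fc_vector()]) with at least two
#'   vectors.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return An object of class `similarity_matrix`: list with `values` (S x S
#'   matrix), `index` (the scan metadata frame) and `metric`.
#' @export
similarity_matrix <- function(fc, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  fc <- fc_set(fc)
  x <- fc$values
  if (nrow(x) < 2L) fail("similarity_matrix needs at least 2 vectors")
  if (metric == "cosine") {
    norms <- sqrt(rowSums(x^2))
    if (any(norms == 0)) fail("cosine similarity is undefined for a zero vector")
    xn <- x / norms
    s <- tcrossprod(xn)
    s <- pmin(pmax((s + t(s)) / 2, -1), 1)
    diag(s) <- 1
  } else {
    s <- -as.matrix(stats::dist(x, method = "euclidean"))
    dimnames(s) <- NULL
    diag(s) <- 0
  }
  structure(list(values = s, index = fc$meta, metric = metric),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "similarity_matrix (%s): %d x %d\n", x$metric,
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Subject identification accuracy by nearest-neighbour matching
#'
#' Every vector whose subject contributed at least one other vector is a
#' query. A query succeeds when the single most similar other vector in the
#' whole cohort (self excluded) belongs to the same subject; an exact tie at
#' the top counts as failure, keeping the statistic deterministic. Vectors
#' from different windows of the same scan count as same-subject — that is
#' precisely the dependence the windowing exploit leverages.
#'
#' @param fc An [fc_set()] (or list of [fc_vector()]).
#' @param metric Similarity metric, as in [similarity_matrix()].
#' @return List with `accuracy` (fraction of successful queries) and
#'   `n_queries`.
#' @export
identification_accuracy <- function(fc, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  fc <- fc_set(fc)
  subjects <- fc$meta$subject_id
  counts <- table(subjects)
  if (!any(counts >= 2L)) {
    fail("identification requires at least one subject with >= 2 vectors")
  }
  sm <- similarity_matrix(fc, metric)$values
  diag(sm) <- -Inf
  queries <- which(counts[subjects] >= 2L)
  successes <- 0L
  for (q in queries) {
    row <- sm[q, ]
    top <- max(row)
    winners <- which(row == top)
    if (length(winners) == 1L && subjects[winners] == subjects[q]) {
      successes <- successes + 1L
    }
  }
  list(accuracy = successes / length(queries), n_queries = length(queries))
}

#' Analytic chance level for subject identification
#'
#' Probability that a uniformly random match of a query among all other
#' vectors hits the same subject: with S subjects and k vectors each, a
#' query has (k - 1) same-subject candidates among (S k - 1) others, giving
#' (k - 1) / (S k - 1).
#'
#' @param n_subjects Number of subjects S.
#' @param scans_per_subject Vectors per subject k (>= 2).
#' @return The chance-level accuracy.
#' @export
chance_level <- function(n_subjects, scans_per_subject) {
  if (!is_count(n_subjects)) fail("n_subjects must be a positive integer")
  if (!is_count(scans_per_subject, min = 2L)) {
    fail("chance_level requires scans_per_subject >= 2")
  }
  (scans_per_subject - 1) / (n_subjects * scans_per_subject - 1)
}
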