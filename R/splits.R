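# Train/test split construction. The whole leakage phenomenon lives here:
# whether dependent samples (scans or windows of one subject) can end up on
# both sides of the split.

unit_key <- function(units) {
  paste(units$subject_id, units$scan_id, ifelse(is.na(units$window_index), "-",
    units$window_index
  ), sep = "\r")
}

#' Extract the sample-unit table of a cohort or fc_set
#'
#' A "unit" is one predictable sample: a scan (static FC) or a window
#' (dynamic FC), identified by `(subject_id, scan_id, window_index)`.
#'
#' @param x An [fc_set()], a cohort list (with a `table` element), or a data
#'   frame already holding the three unit columns.
#' @return Data frame with columns `subject_id`, `scan_id`, `window_index`.
#' @export
sample_units <- function(x) {
  if (inherits(x, "fc_set")) {
    return(x$meta)
  }
  if (is.list(x) && !is.data.frame(x) && !is.null(x$table)) x <- x$table
  if (!is.data.frame(x) || !all(c("subject_id", "scan_id") %in% names(x))) {
    fail("cannot extract sample units: need subject_id and scan_id columns")
  }
  data.frame(
    subject_id = as.character(x$subject_id),
    scan_id = as.character(x$scan_id),
    window_index = if ("window_index" %in% names(x)) {
      as.integer(x$window_index)
    } else {
      rep(NA_integer_, nrow(x))
    },
    stringsAsFactors = FALSE
  )
}

new_split_spec <- function(train, test, leakage_mode, seed) {
  spec <- structure(
    list(
      train = train, test = test,
      leakage_mode = leakage_mode, seed = as.integer(seed)
    ),
    class = "split_spec"
  )
  validate_split_spec(spec)
  spec
}

validate_split_spec <- function(spec) {
  if (length(intersect(unit_key(spec$train), unit_key(spec$test))) > 0) {
    fail("split invariant violated: train and test units overlap")
  }
  if (nrow(spec$train) == 0 || nrow(spec$test) == 0) {
    fail("split invariant violated: empty train or test side")
  }
  both <- intersect(spec$train$subject_id, spec$test$subject_id)
  if (spec$leakage_mode == "subject_disjoint" && length(both) > 0) {
    fail("split invariant violated: subject(s) on both sides of a subject_disjoint split")
  }
  if (spec$leakage_mode == "scan_double_dip") {
    shared_scans <- merge(spec$train[, c("subject_id", "scan_id")],
      spec$test[, c("subject_id", "scan_id")],
      by = c("subject_id", "scan_id")
    )
    if (nrow(shared_scans) > 0) {
      fail("split invariant violated: same (subject, scan) on both sides")
    }
  }
  invisible(spec)
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "split_spec [%s]: %d train / %d test units, %d/%d subjects, seed %d\n",
    x$leakage_mode, nrow(x$train), nrow(x$test),
    length(unique(x$train$subject_id)), length(unique(x$test$subject_id)), x$seed
  ))
  invisible(x)
}

#' Subject-disjoint train/test split (the legitimate protocol)
#'
#' Partitions subjects — not scans — at random; every unit of a subject goes
#' to one side only, so no subject identity information can cross the split.
#'
#' @param units Sample units (see [sample_units()]); an [fc_set()] or cohort
#'   is accepted.
#' @param test_fraction Fraction of subjects assigned to the test side
#'   (default 0.2, i.e. an 80/20 split).
#' @param seed Integer seed for the random subject assignment.
#' @return A `split_spec` with `leakage_mode = "subject_disjoint"`.
#' @export
make_subject_disjoint_split <- function(units, test_fraction = 0.2, seed = 1L) {
  units <- sample_units(units)
  if (!is_scalar_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    fail("test_fraction must be in (0, 1)")
  }
  subjects <- unique(units$subject_id)
  if (length(subjects) < 5L) fail("need at least 5 subjects for a subject-disjoint split")
  n_test <- round(test_fraction * length(subjects))
  n_test <- max(1L, min(length(subjects) - 1L, n_test))
  test_subjects <- with_seed(seed, sample(subjects, n_test))
  new_split_spec(
    train = units[!(units$subject_id %in% test_subjects), , drop = FALSE],
    test = units[units$subject_id %in% test_subjects, , drop = FALSE],
    leakage_mode = "subject_disjoint", seed = seed
  )
}

#' Scan double-dipping split (multi-scan exploit)
#'
#' Treats scans as if they were independent subjects: each multi-scan
#' subject's first scan (lexicographic `scan_id`) goes to train and the
#' second to test, so every subject appears on both sides through different
#' scans; subjects with more than two scans contribute the remainder to
#' train. Single-scan subjects are excluded. Deterministic; `seed` is only
#' recorded (it seeds downstream model randomness such as inner-CV folds).
#'
#' @param units Sample units; scan-level (window-level rows of one scan
#'   follow their scan's side).
#' @param seed Recorded seed.
#' @return A `split_spec` with `leakage_mode = "scan_double_dip"`.
#' @export
make_scan_double_dip_split <- function(units, seed = 0L) {
  units <- sample_units(units)
  scans <- unique(units[, c("subject_id", "scan_id")])
  scans <- scans[order(scans$subject_id, scans$scan_id), , drop = FALSE]
  n_scans <- table(scans$subject_id)
  multi <- names(n_scans)[n_scans >= 2L]
  if (length(multi) == 0) fail("no subject has >= 2 scans; cannot double-dip on scans")
  scans <- scans[scans$subject_id %in% multi, , drop = FALSE]
  rank_within <- stats::ave(seq_len(nrow(scans)), scans$subject_id, FUN = seq_along)
  test_scans <- scans[rank_within == 2L, , drop = FALSE]
  train_scans <- scans[rank_within != 2L, , drop = FALSE]
  pick <- function(side) {
    keep <- paste(units$subject_id, units$scan_id) %in%
      paste(side$subject_id, side$scan_id)
    units[keep, , drop = FALSE]
  }
  new_split_spec(pick(train_scans), pick(test_scans),
    leakage_mode = "scan_double_dip", seed = seed
  )
}

#' Window double-dipping split (single-scan dFC exploit)
#'
#' Treats dFC windows as if they were independent subjects: even
#' `window_index` goes to train, odd to test (a deterministic interleave),
#' so every subject appears on both sides through different windows of the
#' same scan(s).
#'
#' @param units Window-level sample units (all `window_index` non-missing;
#'   every scan must have >= 2 windows).
#' @param seed Recorded seed (as in [make_scan_double_dip_split()]).
#' @return A `split_spec` with `leakage_mode = "window_double_dip"`.
#' @export
make_window_double_dip_split <- function(units, seed = 0L) {
  units <- sample_units(units)
  if (any(is.na(units$window_index))) {
    fail("window double-dipping requires window-level units (no missing window_index)")
  }
  scan_key <- paste(units$subject_id, units$scan_id)
  per_scan <- table(scan_key)
  if (any(per_scan < 2L)) {
    fail("every scan needs >= 2 windows to double-dip on windows")
  }
  even <- units$window_index %% 2L == 0L
  new_split_spec(units[even, , drop = FALSE], units[!even, , drop = FALSE],
    leakage_mode = "window_double_dip", seed = seed
  )
}

#' Random scan-to-side split (the in-between case)
#'
#' Assigns scans (not subjects) to train/test uniformly at random. Some
#' subjects end up with scans on both sides, some not, so the expected
#' leakage — and the resulting accuracy — lies between the subject-disjoint
#' and fully double-dipped protocols.
#'
#' @param units Sample units.
#' @param test_fraction Fraction of scans sent to the test side.
#' @param seed Integer seed.
#' @return A `split_spec` with `leakage_mode = "scan_random"`.
#' @export
make_random_scan_split <- function(units, test_fraction = 0.2, seed = 1L) {
  units <- sample_units(units)
  if (!is_scalar_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    fail("test_fraction must be in (0, 1)")
  }
  scans <- unique(paste(units$subject_id, units$scan_id))
  if (length(scans) < 2L) fail("need at least 2 scans")
  n_test <- max(1L, min(length(scans) - 1L, round(test_fraction * length(scans))))
  test_scans <- with_seed(seed, sample(scans, n_test))
  in_test <- paste(units$subject_id, units$scan_id) %in% test_scans
  new_split_spec(units[!in_test, , drop = FALSE], units[in_test, , drop = FALSE],
    leakage_mode = "scan_random", seed = seed
  )
}
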