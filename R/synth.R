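#' Configuration of a synthetic multi-scan cohort
#'
#' Defines the generative model for a synthetic resting-state cohort. Each
#' scan's target correlation matrix is assembled in Fisher-z space as
#' \deqn{Z_{is} = Z_{base} + \alpha F_i + \beta y_i W + \sigma E_{is}}
#' where \eqn{Z_{base}} is a cohort-common backbone, \eqn{F_i} a low-rank
#' subject fingerprint (fixed across a subject's scans), \eqn{W} a fixed
#' phenotype-loading pattern scaled by the subject's standardized phenotype
#' \eqn{y_i}, and \eqn{E_{is}} per-scan session noise. \eqn{F_i}, \eqn{W} and
#' \eqn{E_{is}} are symmetric, zero-diagonal and normalized to unit Frobenius
#' norm, so `alpha_fingerprint`, `beta_phenotype` and `sigma_session` are
#' directly comparable component amplitudes on the Fisher-z scale,
#' independent of the number of regions.
#'
#' @param n_subjects Number of subjects.
#' @param scans_per_subject Scans per subject (>= 1).
#' @param n_rois Number of regions P (>= 3).
#' @param n_timepoints Timeseries length T; must be >= 2 * n_rois when
#'   timeseries are generated so the sample correlation is well conditioned.
#' @param tr_seconds Repetition time in seconds.
#' @param alpha_fingerprint Amplitude of the subject-stable fingerprint
#'   component (Fisher-z scale, >= 0). This is what makes scans of the same
#'   subject identifiable.
#' @param beta_phenotype Amplitude of the phenotype-linked component
#'   (Fisher-z scale, >= 0). This is what legitimate prediction uses.
#' @param sigma_session Amplitude of per-scan session noise (Fisher-z scale,
#'   >= 0).
#' @param fingerprint_rank Rank of the subject fingerprint perturbation.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param structure_seed Seed for the cohort-level structure (backbone
#'   `Z_base` and phenotype pattern `W`). Defaults to an offset of `seed`.
#'   Two cohorts built with the same `structure_seed` but different `seed`
#'   share the backbone and phenotype loading while having independent
#'   subjects — the setting used by cross-cohort experiments.
#'
#' @return An object of class `synth_config`.
#' @seealso [generate_cohort()], [generate_fc_cohort()]
#' @export
synth_config <- function(n_subjects = 50, scans_per_subject = 2, n_rois = 30,
                         n_timepoints = 200, tr_seconds = 2,
                         alpha_fingerprint = 1.0, beta_phenotype = 0.5,
                         sigma_session = 0.5, fingerprint_rank = 3,
                         seed = 1L, structure_seed = NULL) {
  if (!is_count(n_subjects)) fail("n_subjects must be a positive integer")
  if (!is_count(scans_per_subject)) fail("scans_per_subject must be >= 1")
  if (!is_count(n_rois, min = 3L)) fail("n_rois must be an integer >= 3")
  if (!is_count(n_timepoints, min = 2L)) fail("n_timepoints must be an integer >= 2")
  if (!is_scalar_number(tr_seconds) || tr_seconds <= 0) fail("tr_seconds must be > 0")
  for (nm in c("alpha_fingerprint", "beta_phenotype", "sigma_session")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) fail("%s must be a nonnegative number", nm)
  }
  if (!is_count(fingerprint_rank)) fail("fingerprint_rank must be a positive integer")
  if (!is_count(seed, min = -.Machine$integer.max)) fail("seed must be an integer")
  if (is.null(structure_seed)) {
    structure_seed <- (abs(seed) + 1000000L) %% .Machine$integer.max
  }
  if (!is_count(structure_seed, min = -.Machine$integer.max)) {
    fail("structure_seed must be an integer")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      scans_per_subject = as.integer(scans_per_subject),
      n_rois = as.integer(n_rois),
      n_timepoints = as.integer(n_timepoints),
      tr_seconds = as.numeric(tr_seconds),
      alpha_fingerprint = as.numeric(alpha_fingerprint),
      beta_phenotype = as.numeric(beta_phenotype),
      sigma_session = as.numeric(sigma_session),
      fingerprint_rank = as.integer(fingerprint_rank),
      seed = as.integer(seed),
      structure_seed = as.integer(structure_seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synth_config: %d subjects x %d scans, P=%d, T=%d (TR=%gs)\n",
    x$n_subjects, x$scans_per_subject, x$n_rois, x$n_timepoints, x$tr_seconds
  ))
  cat(sprintf(
    "  alpha (fingerprint) = %g, beta (phenotype) = %g, sigma (session) = %g, rank = %d\n",
    x$alpha_fingerprint, x$beta_phenotype, x$sigma_session, x$fingerprint_rank
  ))
  cat(sprintf("  seed = %d, structure_seed = %d\n", x$seed, x$structure_seed))
  invisible(x)
}

#' One scan's ROI timeseries
#'
#' Container for a single scan: a T x P matrix of BOLD-like signal with
#' subject/scan identity and the repetition time.
#'
#' @param values Numeric T x P matrix, all entries finite. Column names are
#'   ROI labels (defaulted to ROI1..ROIP when absent).
#' @param subject_id,scan_id Identity tokens.
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id, scan_id, tr_seconds) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    fail("roi_timeseries values must be a finite numeric matrix")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("ROI", seq_len(ncol(values)))
  }
  if (!is_scalar_number(tr_seconds) || tr_seconds <= 0) fail("tr_seconds must be > 0")
  structure(
    list(
      values = values,
      subject_id = as.character(subject_id),
      scan_id = as.character(scan_id),
      tr_seconds = as.numeric(tr_seconds)
    ),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "roi_timeseries %s/%s: %d timepoints x %d ROIs, TR=%gs\n",
    x$subject_id, x$scan_id, nrow(x$values), ncol(x$values), x$tr_seconds
  ))
  invisible(x)
}

# ---- internal generative machinery ----------------------------------------

# Symmetric zero-diagonal matrix with i.i.d. N(mean, sd) upper triangle.
rand_symmetric <- function(p, mean = 0, sd = 1) {
  m <- matrix(0, p, p)
  ut <- upper.tri(m)
  m[ut] <- stats::rnorm(sum(ut), mean = mean, sd = sd)
  m + t(m)
}

unit_frobenius <- function(m) {
  nf <- sqrt(sum(m^2))
  if (nf == 0) fail("cannot normalize an all-zero matrix")
  m / nf
}

# Low-rank symmetric perturbation: sum_k u_k u_k^T with each u_k an i.i.d.
# normal direction scaled to unit Euclidean norm, diagonal zeroed. The
# per-direction normalization makes the component amplitudes comparable
# across P (each rank-one term has unit Frobenius norm). Used for subject
# fingerprints (rank = fingerprint_rank) and the phenotype loading pattern
# (rank 1).
rand_lowrank_pattern <- function(p, rank) {
  m <- matrix(0, p, p)
  for (k in seq_len(rank)) {
    u <- stats::rnorm(p)
    m <- m + tcrossprod(u / sqrt(sum(u^2)))
  }
  diag(m) <- 0
  m
}

# Cohort backbone: a modular ("network") block correlation structure, as in
# real parcellated FC — within-module edges strong, between-module edges
# weak. Built as 0.10 + 0.35 * same-module, which is positive definite by
# construction (a sum of scaled all-ones blocks plus the identity), then
# moved to Fisher-z space with a small seeded jitter. Keeping the backbone
# close to a valid correlation matrix matters: the per-scan perturbations
# are small, so tanh(Z_is) stays near-PSD and the nearest-correlation
# projection barely moves it. A backbone far from PSD would make the
# projection itself a large, scan-specific distortion that swamps the
# fingerprint.
backbone_z <- function(p, n_modules = 5L, jitter_sd = 0.03) {
  modules <- (sample(p) %% n_modules) + 1L
  r <- 0.10 + 0.35 * outer(modules, modules, "==")
  diag(r) <- 1
  diag(r) <- 0 # the z-space diagonal is unused; tanh(0) = 0 and diag is reset to 1 downstream
  atanh(r) + rand_symmetric(p, mean = 0, sd = jitter_sd)
}

# Draws everything up to (and including) the per-scan Fisher-z target
# matrices. Both cohort generators share this, so the fast FC path and the
# timeseries path agree on Z_is exactly.
simulate_z_cohort <- function(config) {
  p <- config$n_rois
  structure_part <- with_seed(config$structure_seed, {
    list(
      z_base = backbone_z(p),
      w = rand_lowrank_pattern(p, rank = 1L)
    )
  })
  with_seed(config$seed, {
    y <- stats::rnorm(config$n_subjects)
    subjects <- sprintf("sub%03d", seq_len(config$n_subjects))
    scans <- sprintf("scan%02d", seq_len(config$scans_per_subject))
    z_list <- vector("list", config$n_subjects * config$scans_per_subject)
    rows <- vector("list", length(z_list))
    idx <- 0L
    for (i in seq_len(config$n_subjects)) {
      f_i <- rand_lowrank_pattern(p, rank = config$fingerprint_rank)
      for (s in seq_len(config$scans_per_subject)) {
        e_is <- unit_frobenius(rand_symmetric(p, mean = 0, sd = 1))
        z <- structure_part$z_base +
          config$alpha_fingerprint * f_i +
          config$beta_phenotype * y[i] * structure_part$w +
          config$sigma_session * e_is
        idx <- idx + 1L
        z_list[[idx]] <- z
        rows[[idx]] <- data.frame(
          subject_id = subjects[i], scan_id = scans[s],
          phenotype_cont = y[i], phenotype_bin = as.integer(y[i] > 0),
          stringsAsFactors = FALSE
        )
      }
    }
    list(z = z_list, table = do.call(rbind, rows))
  })
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Symmetrizes, eigen-decomposes, clips eigenvalues at `eig_floor`,
#' reconstructs, and rescales to unit diagonal. Deterministic and cheap at
#' the matrix sizes this package works with.
#'
#' @param m Square numeric matrix.
#' @param eig_floor Lower clip for eigenvalues.
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_correlation <- function(m, eig_floor = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(r)
  if (any(d <= 0)) {
    fail("projection produced a non-positive diagonal; component scales too extreme")
  }
  r <- r / sqrt(outer(d, d))
  diag(r) <- 1
  (r + t(r)) / 2
}

# Sample n rows from N(0, C) via eigen decomposition (deterministic given
# the RNG state; avoids dependence on a specific chol pivoting).
sample_mvn <- function(n, c_mat) {
  e <- eigen(c_mat, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(c_mat)), nrow = n)
  z %*% (t(e$vectors) * sqrt(vals))
}

#' Generate a synthetic multi-scan cohort of ROI timeseries
#'
#' Draws each subject's standardized phenotype, assembles per-scan target
#' correlation matrices in Fisher-z space (see [synth_config()]), maps them
#' back through `tanh`, projects to the nearest valid correlation matrix,
#' and samples a zero-mean multivariate normal timeseries per scan.
#' Fully deterministic given the config.
#'
#' @param config A [synth_config()].
#' @return A list with elements `scans` (list of [roi_timeseries()], one per
#'   subject/scan) and `table` (the cohort table: one row per scan with
#'   `subject_id`, `scan_id`, `phenotype_cont`, `phenotype_bin`; phenotypes
#'   are constant across a subject's scans).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_timepoints < 2L * config$n_rois) {
    fail(
      "n_timepoints (%d) must be >= 2 * n_rois (%d) for timeseries generation",
      config$n_timepoints, 2L * config$n_rois
    )
  }
  sim <- simulate_z_cohort(config)
  scans <- with_seed(config$seed + 500000L, {
    lapply(seq_along(sim$z), function(k) {
      r_target <- tanh(sim$z[[k]])
      diag(r_target) <- 1
      r_valid <- nearest_correlation(r_target)
      x <- sample_mvn(config$n_timepoints, r_valid)
      colnames(x) <- paste0("ROI", seq_len(config$n_rois))
      roi_timeseries(
        x,
        subject_id = sim$table$subject_id[k],
        scan_id = sim$table$scan_id[k],
        tr_seconds = config$tr_seconds
      )
    })
  })
  list(scans = scans, table = sim$table)
}

#' Generate a cohort of connectivity vectors directly (fast path)
#'
#' Skips timeseries sampling: the per-scan Fisher-z targets are mapped back
#' to correlations with `tanh` and vectorized (row-major strict upper
#' triangle, the package-wide convention). Identical generative parameters
#' and identical Fisher-z draws as [generate_cohort()] for the same config;
#' `n_timepoints` is ignored. Useful when the question is about FC-space
#' structure rather than sampling noise.
#'
#' @param config A [synth_config()].
#' @return A list with elements `fc` (an [fc_set()]) and `table` (cohort
#'   table as in [generate_cohort()]).
#' @export
generate_fc_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sim <- simulate_z_cohort(config)
  values <- t(vapply(sim$z, function(z) {
    r <- tanh(z)
    diag(r) <- 1
    vectorize_fc(r)
  }, numeric(config$n_rois * (config$n_rois - 1L) / 2L)))
  fc <- new_fc_set(
    values = values,
    meta = data.frame(
      subject_id = sim$table$subject_id,
      scan_id = sim$table$scan_id,
      window_index = NA_integer_,
      stringsAsFactors = FALSE
    ),
    n_rois = config$n_rois
  )
  list(fc = fc, table = sim$table)
}

#' Write a cohort to disk (one delimited file per scan plus a manifest)
#'
#' Each scan is written as a CSV of T rows x P columns with a header row of
#' ROI labels; the manifest CSV lists `subject_id`, `scan_id`, `path`
#' (relative to the manifest), `tr_seconds` and the phenotypes.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  rel_paths <- character(length(cohort$scans))
  for (k in seq_along(cohort$scans)) {
    ts <- cohort$scans[[k]]
    rel_paths[k] <- file.path("scans", sprintf("%s_%s.csv", ts$subject_id, ts$scan_id))
    utils::write.csv(as.data.frame(ts$values), file.path(dir, rel_paths[k]),
      row.names = FALSE
    )
  }
  manifest <- cbind(
    cohort$table[, c("subject_id", "scan_id")],
    path = rel_paths,
    tr_seconds = vapply(cohort$scans, `[[`, numeric(1), "tr_seconds"),
    cohort$table[, c("phenotype_cont", "phenotype_bin")]
  )
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort back from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list with `scans` and `table`, as [generate_cohort()] returns.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  scans <- lapply(seq_len(nrow(manifest)), function(k) {
    vals <- as.matrix(utils::read.csv(file.path(base, manifest$path[k])))
    roi_timeseries(vals, manifest$subject_id[k], manifest$scan_id[k],
      tr_seconds = manifest$tr_seconds[k]
    )
  })
  table <- manifest[, c("subject_id", "scan_id", "phenotype_cont", "phenotype_bin")]
  list(scans = scans, table = table)
}
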