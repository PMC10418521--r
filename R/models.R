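# Phenotype prediction and the three experimental arms: null model,
# legitimate (subject-disjoint) prediction, and double-dipping prediction.
# Ridge-penalized linear / logistic regression via glmnet; one regularization
# hyperparameter chosen on a powers-of-ten grid by inner 5-fold CV on the
# training set only.

lambda_grid <- function() 10^seq(4, -4) # decreasing, 9 grid points

# Standardize columns by train statistics only; zero-variance columns get
# scale 1 so they become constant-zero features (harmless under ridge).
train_standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd == 0] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, sd, "/")
}

target_vector <- function(units, cohort_table, task) {
  col <- if (task == "classification") "phenotype_bin" else "phenotype_cont"
  pheno <- unique(cohort_table[, c("subject_id", col)])
  if (anyDuplicated(pheno$subject_id)) {
    fail("phenotype differs across scans of the same subject")
  }
  y <- pheno[[col]][match(units$subject_id, pheno$subject_id)]
  if (any(is.na(y))) fail("split contains subjects absent from the cohort table")
  y
}

metric_of <- function(pred, truth, task) {
  if (task == "classification") mean(pred == truth) else sqrt(mean((pred - truth)^2))
}

glmnet_predict <- function(x_train, y_train, x_new, task, lambdas) {
  family <- if (task == "classification") "binomial" else "gaussian"
  fit <- withCallingHandlers(
    glmnet::glmnet(x_train, y_train,
      family = family, alpha = 0,
      lambda = lambdas, standardize = FALSE
    ),
    # inner-CV folds at desk scale are legitimately small; glmnet warns on
    # binomial fits with < 8 per-class observations
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  pred <- stats::predict(fit, newx = x_new, s = lambdas, type = "response")
  if (task == "classification") pred <- (pred > 0.5) * 1
  pred # matrix: rows = new samples, cols = lambdas
}

# Stratified (by class, for classification) fold assignment.
make_folds <- function(y, n_folds, task, seed) {
  with_seed(seed, {
    folds <- integer(length(y))
    groups <- if (task == "classification") split(seq_along(y), y) else list(seq_along(y))
    for (idx in groups) {
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    folds
  })
}

# Core fit: inner-CV hyperparameter choice on train, refit, test metric.
fit_core <- function(x_train, y_train, x_test, y_test, task, seed, n_folds = 5L) {
  lambdas <- lambda_grid()
  if (task == "classification" && length(unique(y_train)) < 2L) {
    fail("training set contains a single class")
  }
  folds <- make_folds(y_train, n_folds, task, seed)
  cv_metric <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    std <- train_standardizer(x_train[tr, , drop = FALSE])
    pred <- glmnet_predict(
      std(x_train[tr, , drop = FALSE]), y_train[tr],
      std(x_train[!tr, , drop = FALSE]), task, lambdas
    )
    cv_metric[f, ] <- apply(pred, 2, metric_of, truth = y_train[!tr], task = task)
  }
  mean_metric <- colMeans(cv_metric)
  # best lambda; ties broken toward stronger regularization (smaller index)
  best <- if (task == "classification") {
    which.max(mean_metric)
  } else {
    which.min(mean_metric)
  }
  lambda <- lambdas[best]
  std <- train_standardizer(x_train)
  pred <- glmnet_predict(std(x_train), y_train, std(x_test), task, lambdas)[, best]
  list(
    metric = metric_of(pred, y_test, task),
    lambda = lambda,
    predictions = as.numeric(pred),
    truth = y_test
  )
}

split_features <- function(fc, split) {
  keys <- unit_key(fc$meta)
  get_side <- function(side) {
    idx <- match(unit_key(side), keys)
    if (any(is.na(idx))) fail("split refers to units absent from the fc_set")
    fc$values[idx, , drop = FALSE]
  }
  list(train = get_side(split$train), test = get_side(split$test))
}

#' Fit a regularized model on a split and score it on the test side
#'
#' Features are standardized using training-set statistics only. The ridge
#' penalty is chosen from a powers-of-ten grid (1e-4 ... 1e4, 9 points) by
#' inner 5-fold cross-validation on the training set, the model is refit on
#' the full training side, and the test-side metric is returned: accuracy
#' for classification (ridge-penalized logistic regression on the binary
#' phenotype) or RMSE for regression (ridge regression on the continuous
#' phenotype).
#'
#' @param fc An [fc_set()] containing every unit the split names.
#' @param cohort_table Cohort table with per-subject phenotypes.
#' @param split A `split_spec`.
#' @param task `"classification"` or `"regression"`.
#' @param seed Seed for the inner-CV fold assignment; defaults to the
#'   split's seed.
#' @return List with `metric`, `lambda` (chosen penalty), `predictions` and
#'   `truth` for the test side.
#' @export
fit_predict <- function(fc, cohort_table, split, task = c("classification", "regression"),
                        seed = split$seed) {
  task <- match.arg(task)
  fc <- fc_set(fc)
  stopifnot(inherits(split, "split_spec"))
  xs <- split_features(fc, split)
  fit_core(
    xs$train, target_vector(split$train, cohort_table, task),
    xs$test, target_vector(split$test, cohort_table, task),
    task, seed
  )
}

#' Null-model baseline for a split
#'
#' Classification: the frequency of the training side's majority class in
#' the test side. Regression: test-side RMSE of predicting the training-side
#' mean. This is the "no information beyond the marginal target
#' distribution" reference any real model must beat.
#'
#' @inheritParams fit_predict
#' @return The null metric (accuracy or RMSE).
#' @export
null_metric <- function(cohort_table, split, task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(inherits(split, "split_spec"))
  y_train <- target_vector(split$train, cohort_table, task)
  y_test <- target_vector(split$test, cohort_table, task)
  if (task == "classification") {
    counts <- table(y_train)
    majority <- as.numeric(names(counts)[which.max(counts)]) # ties: lower label
    mean(y_test == majority)
  } else {
    sqrt(mean((y_test - mean(y_train))^2))
  }
}

arm_of_mode <- function(mode) {
  switch(mode,
    subject_disjoint = "legitimate",
    cross_cohort = "legitimate",
    scan_double_dip = "double_dip",
    window_double_dip = "double_dip",
    scan_random = "random",
    fail("unknown leakage mode '%s'", mode)
  )
}

new_experiment_result <- function(task, arm, metrics, lambdas, n_train, n_test,
                                  leakage_mode) {
  structure(
    list(
      task = task, arm = arm, leakage_mode = leakage_mode,
      per_iteration_metric = metrics,
      metric_mean = mean(metrics),
      metric_sd = if (length(metrics) > 1L) stats::sd(metrics) else 0,
      n_train = n_train, n_test = n_test,
      chosen_hyperparameter = lambdas
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  metric_name <- if (x$task == "classification") "accuracy" else "RMSE"
  cat(sprintf(
    "experiment_result [%s, %s]: %s %.3f +/- %.3f over %d iterations (n_train=%d, n_test=%d)\n",
    x$arm, x$task, metric_name, x$metric_mean, x$metric_sd,
    length(x$per_iteration_metric), x$n_train, x$n_test
  ))
  invisible(x)
}

#' Monte-Carlo re-splitting experiment (one arm)
#'
#' Repeats split construction and model fitting `n_iterations` times with
#' seeds `base_seed + 1, ..., base_seed + n_iterations` and aggregates the
#' test metric. For stochastic split makers (subject-disjoint, random-scan)
#' every iteration re-splits the cohort; for the deterministic double-dip
#' makers the split is fixed and iterations vary only the inner-CV fold
#' assignment.
#'
#' @param fc An [fc_set()].
#' @param cohort_table Cohort table with phenotypes.
#' @param split_maker Function `(units, seed) -> split_spec`, e.g.
#'   [make_subject_disjoint_split()] or [make_scan_double_dip_split()].
#' @param task `"classification"` or `"regression"`.
#' @param n_iterations Number of re-splits (default 20).
#' @param base_seed Base seed.
#' @return An `experiment_result` with per-iteration metrics, their mean and
#'   sd, and the chosen penalty per iteration.
#' @export
run_bootstrap <- function(fc, cohort_table, split_maker,
                          task = c("classification", "regression"),
                          n_iterations = 20L, base_seed = 1L) {
  task <- match.arg(task)
  fc <- fc_set(fc)
  if (!is_count(n_iterations)) fail("n_iterations must be a positive integer")
  units <- sample_units(fc)
  metrics <- numeric(n_iterations)
  lambdas <- numeric(n_iterations)
  split <- NULL
  for (i in seq_len(n_iterations)) {
    split <- split_maker(units, seed = base_seed + i)
    res <- fit_predict(fc, cohort_table, split, task)
    metrics[i] <- res$metric
    lambdas[i] <- res$lambda
  }
  new_experiment_result(
    task, arm_of_mode(split$leakage_mode), metrics, lambdas,
    n_train = nrow(split$train), n_test = nrow(split$test),
    leakage_mode = split$leakage_mode
  )
}

#' Cross-cohort experiment (train on A, test on B)
#'
#' The mitigation protocol: fit on every unit of cohort A and score on every
#' unit of cohort B. No split randomness; since no subject appears in both
#' cohorts, subject memorization cannot transfer, and any accuracy above the
#' null reflects genuine phenotype signal (shared generative `W`).
#'
#' @param fc_a,fc_b [fc_set()]s of the two cohorts (same `n_rois`).
#' @param table_a,table_b Their cohort tables (same phenotype definition).
#' @param task `"classification"` or `"regression"`.
#' @param seed Seed for the inner-CV fold assignment.
#' @return An `experiment_result` (single iteration, arm `"legitimate"`,
#'   leakage mode `"cross_cohort"`).
#' @export
run_cross_cohort <- function(fc_a, table_a, fc_b, table_b,
                             task = c("classification", "regression"), seed = 1L) {
  task <- match.arg(task)
  fc_a <- fc_set(fc_a)
  fc_b <- fc_set(fc_b)
  if (fc_a$n_rois != fc_b$n_rois) {
    fail("cohorts have different feature lengths (P=%d vs P=%d)", fc_a$n_rois, fc_b$n_rois)
  }
  res <- fit_core(
    fc_a$values, target_vector(fc_a$meta, table_a, task),
    fc_b$values, target_vector(fc_b$meta, table_b, task),
    task, seed
  )
  new_experiment_result(task, "legitimate",
    metrics = res$metric, lambdas = res$lambda,
    n_train = nrow(fc_a$values), n_test = nrow(fc_b$values),
    leakage_mode = "cross_cohort"
  )
}

experiment_summary <- function(x) {
  if (inherits(x, "experiment_result")) {
    c(mean = x$metric_mean, sd = x$metric_sd)
  } else if (is_scalar_number(x)) {
    c(mean = as.numeric(x), sd = NA_real_)
  } else {
    fail("expected an experiment_result or a single number")
  }
}

#' Inflation attributable to double-dipping
#'
#' Compares the legitimate and double-dipping arms against the null
#' baseline. For classification the improvement is the accuracy gap in
#' percentage points, `(dd - legit) * 100`. For regression it is the RMSE
#' reduction relative to the null-model RMSE,
#' `(legit - dd) / null * 100` — the share of the no-information error scale
#' that double-dipping appears to remove on top of the legitimate model.
#'
#' @param legit,dd The legitimate and double-dipping results: either
#'   `experiment_result` objects or plain metric values.
#' @param null Null-model metric (accuracy or RMSE).
#' @param task Required when `legit`/`dd` are plain numbers; otherwise taken
#'   from the results (which must agree).
#' @return One-row data frame: task, null metric, mean and sd per arm, and
#'   `improvement` (percentage points for classification, percent of null
#'   RMSE for regression).
#' @export
inflation_report <- function(legit, dd, null, task = NULL) {
  tasks <- c(
    if (inherits(legit, "experiment_result")) legit$task,
    if (inherits(dd, "experiment_result")) dd$task,
    task
  )
  if (length(unique(tasks)) > 1L) fail("legit and dd results are for different tasks")
  if (length(tasks) == 0) fail("task must be given when passing plain metric values")
  task <- match.arg(unique(tasks), c("classification", "regression"))
  l <- experiment_summary(legit)
  d <- experiment_summary(dd)
  if (!is_scalar_number(null)) fail("null must be a single metric value")
  improvement <- if (task == "classification") {
    (d[["mean"]] - l[["mean"]]) * 100
  } else {
    (l[["mean"]] - d[["mean"]]) / null * 100
  }
  data.frame(
    task = task,
    null_metric = null,
    legitimate_mean = l[["mean"]], legitimate_sd = l[["sd"]],
    double_dip_mean = d[["mean"]], double_dip_sd = d[["sd"]],
    improvement = improvement,
    improvement_units = if (task == "classification") "percentage_points" else "percent_of_null_rmse",
    stringsAsFactors = FALSE
  )
}
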