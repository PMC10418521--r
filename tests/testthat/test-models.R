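test_that("null metrics follow the marginal target distribution", {
  units <- data.frame(
    subject_id = sprintf("sub%03d", 1:20), scan_id = "scan01",
    window_index = NA_integer_, stringsAsFactors = FALSE
  )
  table <- data.frame(
    subject_id = units$subject_id,
    scan_id = units$scan_id,
    phenotype_cont = c(rnorm(19), 100), # last subject is an outlier in test
    phenotype_bin = rep(c(1, 0), times = c(12, 8)),
    stringsAsFactors = FALSE
  )
  sp <- fcleakage:::new_split_spec(units[1:15, ], units[16:20, ],
    leakage_mode = "subject_disjoint", seed = 1
  )
  # classification: train is subjects 1..15 (12 ones, 3 zeros) -> majority 1;
  # test holds subjects 16..20, all labelled 0 -> accuracy 0
  expect_equal(null_metric(table, sp, "classification"), 0)
  # balanced labels: accuracy of the majority class frequency in test
  table$phenotype_bin <- rep(c(0, 1), 10)
  expect_equal(
    null_metric(table, sp, "classification"),
    mean(table$phenotype_bin[16:20] == 0)
  )
  # 60/40 imbalance, test mirrors train composition -> 0.6
  table$phenotype_bin <- rep(c(1, 1, 1, 0, 0), 4)
  expect_equal(null_metric(table, sp, "classification"), 0.6)
  # regression: RMSE of predicting the train mean
  mu <- mean(table$phenotype_cont[1:15])
  expect_equal(
    null_metric(table, sp, "regression"),
    sqrt(mean((table$phenotype_cont[16:20] - mu)^2))
  )
})

test_that("null RMSE of a standardized target approaches 1 at scale", {
  cfg <- synth_config(n_subjects = 200, scans_per_subject = 1, n_rois = 4, seed = 8)
  g <- generate_fc_cohort(cfg)
  sp <- make_subject_disjoint_split(sample_units(g$fc), 0.5, seed = 1)
  expect_equal(null_metric(g$table, sp, "regression"), 1, tolerance = 0.15)
})

test_that("fit_predict matches a hand-rolled train-standardized glmnet pipeline", {
  # wiring oracle: standardization from train stats only, ridge at the
  # chosen penalty, prediction on untouched test rows
  cfg <- synth_config(n_subjects = 20, scans_per_subject = 1, n_rois = 8, seed = 5)
  g <- generate_fc_cohort(cfg)
  sp <- make_subject_disjoint_split(sample_units(g$fc), 0.25, seed = 2)
  res <- fit_predict(g$fc, g$table, sp, "regression", seed = 2)
  idx_tr <- match(sp$train$subject_id, g$fc$meta$subject_id)
  idx_te <- match(sp$test$subject_id, g$fc$meta$subject_id)
  x_tr <- g$fc$values[idx_tr, ]
  x_te <- g$fc$values[idx_te, ]
  mu <- colMeans(x_tr)
  sd_ <- apply(x_tr, 2, sd)
  sd_[sd_ == 0] <- 1
  zs <- function(x) sweep(sweep(x, 2, mu), 2, sd_, "/")
  fit <- glmnet::glmnet(zs(x_tr), g$table$phenotype_cont[idx_tr],
    alpha = 0, lambda = 10^seq(4, -4), standardize = FALSE
  )
  manual <- as.numeric(stats::predict(fit, newx = zs(x_te), s = res$lambda))
  expect_equal(res$predictions, manual, tolerance = 1e-6)
  expect_equal(res$metric, sqrt(mean((manual - g$table$phenotype_cont[idx_te])^2)),
    tolerance = 1e-6
  )
})

test_that("a strong noiseless phenotype is predicted almost perfectly when subject-disjoint", {
  cfg <- synth_config(
    n_subjects = 40, scans_per_subject = 2, n_rois = 16,
    alpha_fingerprint = 0, sigma_session = 0, beta_phenotype = 2, seed = 6
  )
  g <- generate_fc_cohort(cfg)
  sp <- make_subject_disjoint_split(sample_units(g$fc), 0.2, seed = 4)
  cls <- fit_predict(g$fc, g$table, sp, "classification")
  expect_gte(cls$metric, 0.95)
  reg <- fit_predict(g$fc, g$table, sp, "regression")
  expect_lt(reg$metric, 0.1)
})

test_that("permuted labels drive subject-disjoint accuracy to chance", {
  cfg <- synth_config(n_subjects = 30, scans_per_subject = 2, n_rois = 10, seed = 3)
  g <- generate_fc_cohort(cfg)
  tab <- g$table
  perm <- fcleakage:::with_seed(99, sample(nrow(tab)))
  tab$phenotype_bin <- stats::ave(tab$phenotype_bin[perm], tab$subject_id,
    FUN = function(v) v[1]
  ) # keep per-subject constancy, destroy any FC link
  res <- run_bootstrap(g$fc, tab, make_subject_disjoint_split, "classification",
    n_iterations = 10, base_seed = 5
  )
  expect_lt(abs(res$metric_mean - 0.5), 0.18)
})

test_that("single-class training sets and missing units are rejected", {
  cfg <- synth_config(n_subjects = 8, scans_per_subject = 1, n_rois = 6, seed = 10)
  g <- generate_fc_cohort(cfg)
  tab <- g$table
  tab$phenotype_bin <- 1
  sp <- make_subject_disjoint_split(sample_units(g$fc), 0.25, seed = 1)
  expect_error(fit_predict(g$fc, tab, sp, "classification"), "single class")
  stranger <- sp
  stranger$test$subject_id[1] <- "nobody"
  expect_error(fit_predict(g$fc, g$table, stranger, "classification"), "absent")
})

test_that("run_bootstrap aggregates per-iteration metrics and respects determinism", {
  cfg <- synth_config(n_subjects = 12, scans_per_subject = 2, n_rois = 8, seed = 21)
  g <- generate_fc_cohort(cfg)
  res <- run_bootstrap(g$fc, g$table, make_subject_disjoint_split, "classification",
    n_iterations = 5, base_seed = 7
  )
  expect_length(res$per_iteration_metric, 5)
  expect_equal(res$metric_mean, mean(res$per_iteration_metric))
  expect_equal(res$arm, "legitimate")
  rerun <- run_bootstrap(g$fc, g$table, make_subject_disjoint_split, "classification",
    n_iterations = 5, base_seed = 7
  )
  expect_identical(res, rerun)
  # a fully fixed split + fixed fold seed -> sd exactly 0
  fixed_maker <- function(units, seed) make_scan_double_dip_split(units, seed = 123)
  fixed <- run_bootstrap(g$fc, g$table, fixed_maker, "classification",
    n_iterations = 4, base_seed = 1
  )
  expect_equal(fixed$metric_sd, 0)
  expect_equal(fixed$arm, "double_dip")
})

test_that("bootstrap mean is stable under higher replication", {
  cfg <- synth_config(n_subjects = 20, scans_per_subject = 2, n_rois = 10, seed = 15)
  g <- generate_fc_cohort(cfg)
  small <- run_bootstrap(g$fc, g$table, make_subject_disjoint_split, "classification",
    n_iterations = 10, base_seed = 1
  )
  big <- run_bootstrap(g$fc, g$table, make_subject_disjoint_split, "classification",
    n_iterations = 40, base_seed = 100
  )
  expect_lt(abs(small$metric_mean - big$metric_mean), max(small$metric_sd, 0.02))
})

test_that("cross-cohort transfer carries phenotype signal but not without beta", {
  base <- synth_config(n_subjects = 30, scans_per_subject = 1, n_rois = 12, seed = 1)
  a <- generate_fc_cohort(base)
  # B: same backbone and W, new subjects
  b_cfg <- synth_config(
    n_subjects = 30, scans_per_subject = 1, n_rois = 12, seed = 77,
    structure_seed = base$structure_seed
  )
  b <- generate_fc_cohort(b_cfg)
  with_signal <- run_cross_cohort(a$fc, a$table, b$fc, b$table, "classification")
  expect_gt(with_signal$metric_mean, 0.75)
  # no phenotype component anywhere: transfer accuracy is chance
  zero <- function(seed, structure_seed = NULL) {
    cfg <- synth_config(
      n_subjects = 30, scans_per_subject = 1, n_rois = 12,
      beta_phenotype = 0, seed = seed, structure_seed = structure_seed
    )
    generate_fc_cohort(cfg)
  }
  a0 <- zero(1)
  b0 <- zero(77, structure_seed = synth_config(seed = 1)$structure_seed)
  flat <- run_cross_cohort(a0$fc, a0$table, b0$fc, b0$table, "classification")
  expect_lt(abs(flat$metric_mean - 0.5), 0.2)
  # mismatched feature spaces are rejected
  small <- generate_fc_cohort(synth_config(n_subjects = 30, scans_per_subject = 1, n_rois = 8, seed = 2))
  expect_error(run_cross_cohort(a$fc, a$table, small$fc, small$table), "feature lengths")
})

test_that("inflation_report reproduces the published arithmetic and edge cases", {
  # accuracy rows: improvement in percentage points
  fib <- inflation_report(0.61, 0.86, null = 0.51, task = "classification")
  expect_equal(fib$improvement, 25)
  # RMSE rows: improvement relative to the null-model RMSE
  age <- inflation_report(5.92, 4.97, null = 7.68, task = "regression")
  expect_equal(round(age$improvement, 1), 12.4)
  wrat <- inflation_report(14.45, 11.0, null = 14.6, task = "regression")
  expect_equal(round(wrat$improvement, 1), 23.6)
  # equal arms -> zero improvement
  expect_equal(inflation_report(0.7, 0.7, 0.5, task = "classification")$improvement, 0)
  # mixed tasks are rejected
  cfg <- synth_config(n_subjects = 10, scans_per_subject = 2, n_rois = 6, seed = 1)
  g <- generate_fc_cohort(cfg)
  r1 <- run_bootstrap(g$fc, g$table, make_subject_disjoint_split, "classification", 2, 1)
  r2 <- run_bootstrap(g$fc, g$table, make_subject_disjoint_split, "regression", 2, 1)
  expect_error(inflation_report(r1, r2, 0.5), "different tasks")
})
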