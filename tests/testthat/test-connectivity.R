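make_ts <- function(x, tr = 2) roi_timeseries(x, "subA", "scan01", tr)

test_that("compute_fc matches a brute-force per-pair Pearson loop", {
  set.seed(31)
  x <- matrix(rnorm(50 * 6), 50, 6)
  v <- compute_fc(make_ts(x))
  brute <- c()
  for (i in 1:5) {
    for (j in (i + 1):6) {
      brute <- c(brute, stats::cor(x[, i], x[, j]))
    }
  }
  expect_equal(v$values, brute, tolerance = 1e-12)
  expect_length(v$values, 15)
  expect_true(is.na(v$window_index))
})

test_that("compute_fc respects affine invariance and perfect linear relations", {
  set.seed(8)
  a <- rnorm(60)
  b <- rnorm(60)
  v <- compute_fc(make_ts(cbind(a, 2 * a + 5, b)))
  expect_equal(v$values[1], 1) # corr(a, 2a+5) is exactly 1
  expect_equal(v$values[2], v$values[3], tolerance = 1e-12) # corr(a,b) = corr(2a+5,b)
  v2 <- compute_fc(make_ts(cbind(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10), c(5, 4, 3, 2, 1))))
  expect_equal(v2$values, c(1, -1, -1))
  # general positive affine maps leave the whole vector unchanged
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- sweep(sweep(x, 2, c(2, 0.5, 3, 10), "*"), 2, c(-1, 4, 0, 2), "+")
  expect_equal(compute_fc(make_ts(x))$values, compute_fc(make_ts(y))$values,
    tolerance = 1e-12
  )
})

test_that("compute_fc rejects degenerate input", {
  expect_error(compute_fc(make_ts(cbind(rep(1, 10), rnorm(10)))), "zero-variance")
  expect_error(compute_fc(make_ts(matrix(rnorm(4), 2, 2))), "3 timepoints")
})

test_that("vectorization is row-major upper triangle and round-trips", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 1:6 # column-major fill
  m <- m + t(m)
  diag(m) <- 1
  # row-major upper triangle of this matrix, read off by hand
  expect_equal(vectorize_fc(m), c(1, 2, 4, 3, 5, 6))
  expect_equal(unvectorize_fc(vectorize_fc(m), 4), m)
  set.seed(2)
  v <- runif(45, -1, 1)
  expect_identical(vectorize_fc(unvectorize_fc(v, 10)), v)
  expect_equal(edge_names(3), c("ROI1_ROI2", "ROI1_ROI3", "ROI2_ROI3"))
})

test_that("dFC windowing anchors at TR 0, drops the partial tail, and indexes from 0", {
  set.seed(5)
  x <- matrix(rnorm(230 * 4), 230, 4)
  wins <- compute_dfc(make_ts(x), window_trs = 50)
  expect_length(wins, 4) # floor(230/50)
  expect_equal(vapply(wins, `[[`, integer(1), "window_index"), 0:3)
  # first window is exactly rows 1..50
  expect_equal(wins[[1]]$values, compute_fc(make_ts(x[1:50, ]))$values)
  # single full window equals static FC
  one <- compute_dfc(make_ts(x[1:50, ]), window_trs = 50)
  expect_length(one, 1)
  expect_equal(one[[1]]$values, compute_fc(make_ts(x[1:50, ]))$values)
  expect_error(compute_dfc(make_ts(x[1:30, ]), window_trs = 50), "fewer than one window")
})

test_that("window-mean FC approaches the full-scan FC for a stationary scan", {
  cfg <- synth_config(
    n_subjects = 1, scans_per_subject = 1, n_rois = 10,
    n_timepoints = 500, seed = 12
  )
  ts <- generate_cohort(cfg)$scans[[1]]
  full <- compute_fc(ts)$values
  wins <- compute_dfc(ts, window_trs = 50)
  win_mat <- t(vapply(wins, `[[`, numeric(45), "values"))
  err10 <- max(abs(colMeans(win_mat) - full))
  err1 <- max(abs(win_mat[1, ] - full))
  expect_lt(err10, err1) # averaging windows shrinks the deviation
  expect_lt(err10, 0.12)
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band and DC", {
  tr <- 2
  n <- 600
  tt <- (0:(n - 1)) * tr
  spec <- bandpass_spec(0.01, 0.15, tr)
  gain <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- bandpass_filter(make_ts(cbind(a = x, b = rnorm(n)), tr), spec)$values[, 1]
    mid <- (n %/% 4):(3 * n %/% 4)
    stats::sd(y[mid]) / stats::sd(x[mid])
  }
  # oracle: squared magnitude response of the order-4 Butterworth (applied
  # twice by the forward-backward pass), evaluated from the transfer
  # function H(e^{-iw}) = B(e^{-iw}) / A(e^{-iw}) directly
  bf <- signal::butter(4, c(0.01, 0.15) / (1 / (2 * tr)), type = "pass")
  oracle_gain <- function(f) {
    w <- 2 * pi * f * tr # radians per sample at fs = 1/tr
    ez <- exp(-1i * w * (seq_along(bf$b) - 1))
    abs(sum(bf$b * ez) / sum(bf$a * ez))^2
  }
  expect_gte(gain(0.05), 0.9)
  expect_lte(gain(0.2), 0.1)
  expect_equal(gain(0.05), oracle_gain(0.05), tolerance = 0.02)
  expect_equal(gain(0.2), oracle_gain(0.2), tolerance = 0.02)
  # DC rejection: constant column maps to (nearly) zero everywhere
  dc <- bandpass_filter(make_ts(cbind(a = rep(5, n), b = rnorm(n)), tr), spec)
  expect_lt(max(abs(dc$values[, 1])), 0.05)
  # zero phase: a passband sinusoid is not time-shifted (peak correlation at lag 0)
  x <- sin(2 * pi * 0.05 * tt)
  y <- bandpass_filter(make_ts(cbind(a = x, b = rnorm(n)), tr), spec)$values[, 1]
  ccf_vals <- stats::ccf(x, y, lag.max = 5, plot = FALSE)
  expect_equal(ccf_vals$lag[which.max(ccf_vals$acf)], 0)
})

test_that("band-pass specification and preconditions are validated", {
  expect_error(bandpass_spec(0, 0.15, 2), "low_hz")
  expect_error(bandpass_spec(0.2, 0.1, 2), "high_hz")
  expect_error(bandpass_spec(0.01, 0.3, 2), "Nyquist")
  spec <- bandpass_spec(0.01, 0.15, 2)
  expect_error(
    bandpass_filter(make_ts(matrix(rnorm(20 * 3), 20, 3)), spec),
    "too short"
  )
  expect_error(
    bandpass_filter(make_ts(matrix(rnorm(600), 200, 3), tr = 3), spec),
    "does not match"
  )
})

test_that("filtering changes broadband FC but barely moves in-band FC", {
  tr <- 2
  n <- 400
  spec <- bandpass_spec(0.01, 0.15, tr)
  set.seed(21)
  broadband <- make_ts(matrix(rnorm(n * 5), n, 5), tr)
  fc_raw <- compute_fc(broadband)$values
  fc_filt <- compute_fc(bandpass_filter(broadband, spec))$values
  expect_gt(max(abs(fc_raw - fc_filt)), 0.01) # the filter is in the path
  # a signal already inside the passband: FC moves by < 0.05 per edge
  tt <- (0:(n - 1)) * tr
  carriers <- sapply(c(0.03, 0.05, 0.08, 0.11), function(f) sin(2 * pi * f * tt + f))
  inband <- carriers %*% matrix(rnorm(20), 4, 5) + 0.05 * matrix(rnorm(n * 5), n, 5)
  inband_ts <- make_ts(inband, tr)
  d <- abs(compute_fc(inband_ts)$values -
    compute_fc(bandpass_filter(inband_ts, spec))$values)
  expect_lt(max(d), 0.05)
})

test_that("fc_set round-trips through CSV", {
  cfg <- synth_config(n_subjects = 3, scans_per_subject = 2, n_rois = 6, seed = 4)
  g <- generate_fc_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fc_csv(g$fc, path)
  back <- read_fc_csv(path)
  expect_equal(back$meta, g$fc$meta)
  expect_equal(unname(back$values), unname(g$fc$values), tolerance = 1e-12)
  expect_equal(back$n_rois, 6)
})
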