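# Shared fixtures, built once per test session. The "default study" is the
# package's reference condition: 50 subjects x 2 scans, P = 30, T = 200,
# TR = 2 s, alpha = 1, beta = 0.5, sigma = 0.5, rank 3.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_bandpass <- function(tr = 2) bandpass_spec(0.01, 0.15, tr)

# Full-pipeline fixture: timeseries cohort + band-passed static FC.
default_study <- function() {
  fixture("default_study", function() {
    cfg <- synth_config(seed = 1)
    cohort <- generate_cohort(cfg)
    fc <- cohort_fc(cohort$scans, bandpass = default_bandpass(cfg$tr_seconds))
    list(cfg = cfg, cohort = cohort, fc = fc)
  })
}

# Same conditions with the fingerprint switched off.
no_fingerprint_study <- function() {
  fixture("no_fingerprint_study", function() {
    cfg <- synth_config(alpha_fingerprint = 0, seed = 1)
    cohort <- generate_cohort(cfg)
    fc <- cohort_fc(cohort$scans, bandpass = default_bandpass(cfg$tr_seconds))
    list(cfg = cfg, cohort = cohort, fc = fc)
  })
}

# Small helper: fc_set from a plain matrix of row vectors.
fc_set_from_matrix <- function(x, subjects, scans = NULL, n_rois) {
  if (is.null(scans)) {
    scans <- stats::ave(subjects, subjects, FUN = function(v) {
      sprintf("scan%02d", seq_along(v))
    })
  }
  fc_set(lapply(seq_len(nrow(x)), function(i) {
    fc_vector(x[i, ], subjects[i], scans[i], n_rois = n_rois)
  }))
}
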