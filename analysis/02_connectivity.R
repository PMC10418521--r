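#!/usr/bin/env Rscript
# Stage 2: ROI timeseries -> connectivity vectors.
#
# Band-pass 0.01-0.15 Hz (order-4 Butterworth, zero phase), Pearson
# correlation, row-major upper-triangle vectorization. Static FC uses the
# whole scan; dynamic FC uses non-overlapping 50-TR windows (4 per scan),
# the representation the single-scan exploit needs.

suppressPackageStartupMessages(library(fcleakage))

cfg <- load_config("results/config.yaml")
cohort <- read_cohort(file.path(cfg$output_dir, "manifest.csv"))
bp <- bandpass_spec(cfg$bandpass$low_hz, cfg$bandpass$high_hz, cfg$synth$tr_seconds)

fc <- cohort_fc(cohort$scans, bandpass = bp)
dfc <- cohort_fc(cohort$scans, bandpass = bp, window_trs = cfg$window_trs)
write_fc_csv(fc, file.path(cfg$output_dir, "fc.csv"))
write_fc_csv(dfc, file.path(cfg$output_dir, "dfc.csv"))

cat(sprintf(
  "static FC: %d vectors x %d edges; dFC: %d window vectors (%d per scan)\n",
  nrow(fc$values), ncol(fc$values), nrow(dfc$values),
  nrow(dfc$values) / nrow(fc$values)
))
cat(sprintf(
  "edge correlation range [%.2f, %.2f], mean %.2f\n",
  min(fc$values), max(fc$values), mean(fc$values)
))
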