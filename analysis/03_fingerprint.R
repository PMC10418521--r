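#!/usr/bin/env Rscript
# Stage 3: subject fingerprinting.
#
# For every scan, find the most cosine-similar other scan in the cohort; a
# hit means it belongs to the same subject. Compares against the analytic
# chance level for structureless matching.

suppressPackageStartupMessages(library(fcleakage))

cfg <- load_config("results/config.yaml")
fc <- read_fc_csv(file.path(cfg$output_dir, "fc.csv"))
dfc <- read_fc_csv(file.path(cfg$output_dir, "dfc.csv"))

ia <- identification_accuracy(fc, cfg$metric)
chance <- chance_level(cfg$synth$n_subjects, cfg$synth$scans_per_subject)
ia_w <- identification_accuracy(dfc, cfg$metric)

summary <- list(
  metric = cfg$metric,
  scan_level = list(accuracy = ia$accuracy, n_queries = ia$n_queries, chance = chance),
  window_level = list(accuracy = ia_w$accuracy, n_queries = ia_w$n_queries),
  config_hash = config_hash(cfg)
)
jsonlite::write_json(summary, file.path(cfg$output_dir, "fingerprint.json"),
  auto_unbox = TRUE, digits = NA
)

cat(sprintf(
  "scan-level identification: %.1f%% over %d queries (chance %.1f%%, ratio %.0fx)\n",
  100 * ia$accuracy, ia$n_queries, 100 * chance, ia$accuracy / chance
))
cat(sprintf(
  "window-level identification: %.1f%% over %d queries\n",
  100 * ia_w$accuracy, ia_w$n_queries
))
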