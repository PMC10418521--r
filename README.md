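# fcleakage

Subject fingerprinting and data leakage in functional-connectivity-based
phenotype prediction.

## The problem

Functional connectivity (FC) — the matrix of Pearson correlations between
band-passed BOLD timeseries of brain regions, vectorised over the upper
triangle — identifies individual subjects across scans with high accuracy:
a scan's most cosine-similar other scan, `sim(a,b) = aᵀb / (‖a‖₂‖b‖₂)`,
usually belongs to the same person. When different scans of one subject (or
different dynamic-FC windows of a single scan) are treated as independent
samples and land on both sides of a train/test split, a phenotype
classifier can exploit that identity signal: it memorises subjects seen in
training instead of learning phenotype structure, and reports inflated
accuracy relative to the legitimate, subject-disjoint protocol.

`fcleakage` is for methodologists and reviewers who want this failure mode
reproducible and measurable: it simulates multi-scan cohorts whose
fingerprint (α), phenotype signal (β) and session noise (σ) are separately
controllable amplitudes in Fisher-z space,

    Z_is = Z_base + α·F_i + β·y_i·W + σ·E_is ,   FC_is = tanh(Z_is)

derives static FC and windowed dFC exactly as standard pipelines do
(0.01–0.15 Hz zero-phase Butterworth, Pearson, upper-triangle
vectorisation, non-overlapping 50-TR windows), measures identifiability by
nearest-neighbour cosine matching, and quantifies the inflation across
three experiment arms — null, legitimate (subject-disjoint 80/20, 20
Monte-Carlo re-splits), and double-dipping — plus the cross-cohort
protocol that eliminates it.

## Worked example

The `analysis/` scripts run the full study in order (about a minute total):

```sh
Rscript analysis/01_simulate.R      # synthetic cohort -> results/study/
Rscript analysis/02_connectivity.R  # band-pass + FC/dFC vectors
Rscript analysis/03_fingerprint.R   # identification accuracy
Rscript analysis/04_experiment.R    # leakage experiment, all arms
Rscript analysis/05_cross_cohort.R  # mitigation check
```

Output of stages 3–5 on the default conditions (50 subjects × 2 scans,
P = 30, T = 200, TR = 2 s, α = 1, β = 0.5, σ = 0.5, seed 1):

```
scan-level identification: 40.0% over 100 queries (chance 1.0%, ratio 40x)
window-level identification: 14.0% over 400 queries

multi_scan  classification null 0.30 | legitimate 0.652 +/- 0.097 | double-dip 0.903 +/- 0.026 | inflation 25.1 pts
dfc_window  classification null 0.30 | legitimate 0.682 +/- 0.079 | double-dip 0.804 +/- 0.008 | inflation 12.2 pts
multi_scan  regression     null 1.06 | legitimate 0.579 +/- 0.093 | double-dip 0.459 +/- 0.000 | inflation 11.3 % of null RMSE
dfc_window  regression     null 1.06 | legitimate 0.697 +/- 0.102 | double-dip 0.587 +/- 0.006 | inflation 10.4 % of null RMSE

within-cohort subject-disjoint: 0.652 +/- 0.097
cross-cohort (3 cohorts):       0.773 +/- 0.029
gap 0.121 (1.3 sd of the disjoint arm) -> no fingerprint-driven gain survives
```

Reading: scans are 40× more identifiable than chance, and simply putting
each subject's second scan in the test set lifts classification accuracy
from 0.65 to 0.90 — a 25-point gain with zero extra phenotype information.
The same exploit works through dFC windows of single scans (+12 points).
Training on one cohort and testing on another (no shared subjects) stays at
the legitimate level: the inflation is subject memorisation, nothing else.

The same study is available as one call: `run_pipeline(run_config())`,
configured via YAML (`load_config`); every artifact is stamped with the
config hash and reruns are byte-identical.

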