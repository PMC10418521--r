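---
title: "Fingerprint-driven leakage in connectivity-based prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint-driven leakage in connectivity-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package studies

Functional connectivity (FC) — the matrix of Pearson correlations between
the band-passed BOLD timeseries of brain regions — is remarkably good at
telling *who* a scan came from. Different scans of the same person are more
similar to each other than to anyone else's, often enough that
nearest-neighbour matching identifies the subject far above chance. That
stability is interesting in itself, but it has a sharp methodological
consequence for phenotype prediction: if two scans (or two dynamic-FC
windows of one scan) of the same subject end up on opposite sides of a
train/test split, a model can score well by recognising the *subject* —
whose label it already saw in training — rather than by learning anything
about the phenotype. The apparent accuracy is then inflated relative to
what the same model achieves under a subject-disjoint split, and the edges
or regions it "selects" are fingerprint features, not phenotype features.

`fcleakage` makes this mechanism reproducible at desk scale. It provides a
synthetic-cohort generator whose fingerprint, phenotype and session-noise
components are separately controllable, the standard FC/dFC derivation, the
identification statistic, and the split constructions and experiment arms
needed to measure the inflation — plus the cross-cohort protocol that
removes it.

## The generative model

Each scan's target correlation matrix is assembled additively in Fisher-z
(arctanh) space and mapped back with `tanh`, which keeps every correlation
in (−1, 1) by construction:

    Z_is = Z_base + alpha * F_i + beta * y_i * W + sigma * E_is

* `Z_base` — the cohort-common backbone. It is built as a modular block
  structure (five "networks"; within-module correlation 0.45, between-module
  0.10) with a small seeded Fisher-z jitter (sd 0.03). Two properties
  motivated this choice. Scientifically, parcellated FC really is modular.
  Numerically, the block construction is positive definite by construction,
  so the per-scan targets `tanh(Z_is)` — backbone plus small perturbations —
  are already near-valid correlation matrices and the
  nearest-correlation projection barely moves them. An earlier candidate
  (i.i.d. random Fisher-z entries) is far from positive definite at P = 30;
  the eigenvalue clipping then distorts every scan differently, which acts
  as a large hidden session-noise term and changes the meaning of `sigma`.
* `F_i` — the subject fingerprint: a rank-`fingerprint_rank` symmetric
  perturbation `sum_k u_k u_k'` with each direction `u_k` drawn i.i.d.
  normal and scaled to unit Euclidean norm, diagonal zeroed. Each rank-one
  term has unit Frobenius norm, so `alpha` is an amplitude comparable
  across region counts. `F_i` is drawn once per subject and reused for all
  of that subject's scans — it is exactly what makes scans identifiable.
* `W` — the phenotype loading, a rank-one pattern of the same family, drawn
  once per cohort. The continuous phenotype `y_i` is standard normal; the
  binary phenotype thresholds it at zero, so one generative path serves
  both the ridge (regression) and logistic (classification) arms.
* `E_is` — session noise, an i.i.d. symmetric zero-diagonal matrix redrawn
  per scan and normalised to unit Frobenius norm. The normalisation is a
  deliberate design choice: it puts `sigma` on the same amplitude scale as
  `alpha` and `beta`, so "fingerprint twice as strong as session noise"
  means literally `alpha = 2 * sigma`. Without it, `sigma` would be a
  per-edge standard deviation whose cohort-level magnitude grows with P,
  and the default settings would drown the fingerprint.

The matrix `tanh(Z_is)` (unit diagonal restored) is projected to the
nearest valid correlation matrix — symmetrise, eigen-decompose, clip
eigenvalues at 1e-8, reconstruct, rescale to unit diagonal — and `T`
timepoints are sampled from a zero-mean multivariate normal with that
correlation. The fast path (`generate_fc_cohort`) skips sampling and
returns the vectorised `tanh(Z_is)` directly; it shares the Fisher-z draws
with the timeseries path, so the two views of a config are consistent.

A `structure_seed` (defaulting to an offset of `seed`) controls `Z_base`
and `W` separately from the subject draws. Cohorts sharing a
`structure_seed` share the backbone and the phenotype loading while having
entirely new subjects — the setting the cross-cohort experiment needs.

### Default study conditions

The defaults are 50 subjects x 2 scans, P = 30 regions, T = 200 timepoints
at TR = 2 s, `alpha = 1.0`, `beta = 0.5`, `sigma = 0.5`, rank 3. These were
chosen once as a desk-scale condition in which both legitimate signal and
leakage have room to operate: the real cohorts this emulates are orders of
magnitude larger, and no published fingerprint-to-noise ratio exists to
match, so the defaults aim to bracket the qualitative behaviour (strong but
imperfect identifiability; mid-range legitimate accuracy) rather than any
dataset's numbers. Note that the timeseries path adds Pearson sampling
noise on top of `sigma`: at T = 200 with the 0.01–0.15 Hz band this is the
dominant scan-to-scan perturbation, which is also true of real data at
usual scan lengths.

## Connectivity derivation

* **Filtering.** Order-4 Butterworth band-pass, 0.01–0.15 Hz, applied
  forward and backward (zero phase) to each ROI column. Only the band edges
  are canonical; Butterworth-zero-phase is the field default and makes the
  amplitude-response oracle easy to state. The series is extended by odd
  reflection (up to 100 samples) before filtering because the low-cut poles
  settle slowly; series of 27 or fewer timepoints are rejected.
* **FC.** Pearson correlation over all region pairs, reduced to the strict
  upper triangle and vectorised row-major: (1,2), (1,3), …, (2,3), … Every
  module shares this one convention.
* **dFC.** Non-overlapping windows of 50 TRs anchored at the first
  timepoint, trailing partial window discarded, indexed from 0. The full
  series is filtered before windowing: filtering 50-sample windows
  independently is numerically fragile, and anchoring at 0 is the simplest
  reproducible choice among the conventions the literature leaves open.

## Fingerprinting

Identification uses cosine similarity `sim(a,b) = a'b / (||a|| ||b||)`.
Every vector whose subject has at least one other vector is a query; it
succeeds when the single most similar other vector in the cohort belongs to
the same subject. Exact ties count as failure, keeping the statistic
deterministic. Window-level vectors of one subject count as same-subject
matches — that dependence is precisely what the windowing exploit uses.
The analytic chance level for structureless vectors, with S subjects and k
vectors each, is `(k − 1) / (S k − 1)`; the test suite verifies Monte-Carlo
agreement. Euclidean similarity is available (stored negated so higher
always means more similar); on unit-normalised vectors its ranking
coincides with the cosine ranking.

## The experiment arms

* **Null** — majority-class frequency (classification) or RMSE of the
  train-mean prediction (regression) on the test side.
* **Legitimate** — subjects partitioned 80/20 at random, all scans of a
  subject on one side. Repeated over 20 Monte-Carlo re-splits; "bootstrap"
  here means repeated random re-splitting, not resampling with replacement,
  which keeps each iteration's test set disjoint from its train set.
* **Double-dipping** — every subject's first scan (lexicographic scan id)
  to train and second to test (extra scans to train), or even window
  indices to train and odd to test. Deterministic by design: it represents
  the maximal version of the mistake. Iterations then vary only the inner
  cross-validation folds.
* **Random scan assignment** — scans assigned to sides at random,
  irrespective of subject; its accuracy falls between the legitimate and
  double-dipped arms, because only some subjects straddle the split.
* **Cross-cohort** — train on all of cohort A, test on all of cohort B
  (shared backbone and `W`, disjoint subjects). No subject memorization can
  transfer, so this is the mitigation benchmark.

Models are ridge-penalised logistic regression (classification, accuracy)
and ridge regression (continuous target, RMSE) via `glmnet`. Features are
standardised with training-set statistics only — whole-cohort normalisation
is itself a classic leak and is deliberately not done. The single penalty is
chosen from a powers-of-ten grid (1e-4 … 1e4, nine points) by stratified
inner 5-fold cross-validation on the training side, with ties broken toward
stronger regularisation; the model is refit on the full training side
before scoring.

The inflation statistic follows the conventions of reported leakage
studies: for classification, double-dip minus legitimate accuracy in
percentage points; for regression,
`(legitimate RMSE − double-dip RMSE) / null RMSE`, expressed in percent.
Published reports typically print such percentages without stating the
formula; the relative-to-null convention is adopted here because it
recovers representative published improvement figures from their printed
accuracies and RMSEs, which the test suite asserts.

## Numerical and degenerate-input choices

* Eigenvalue floor 1e-8 in the correlation projection; sampling uses the
  eigen-decomposition (no Cholesky pivoting dependence).
* Zero-variance ROI columns, series shorter than one window, zero vectors
  in cosine similarity, single-class training sets, and splits referring to
  unknown units are all hard errors, not silent repairs.
* Columns with zero training variance standardise to constant zero
  (scale 1), which ridge ignores.
* All randomness flows from explicit seeds; every public generator and
  experiment is bit-reproducible given its config, and the pipeline stamps
  each artifact with a hash of the result-determining configuration fields.

## What the generator does and does not emulate

It emulates the three ingredients the leakage mechanism needs — a stable
subject fingerprint, a phenotype-linked component, session noise — plus a
modular backbone and finite-scan Pearson sampling noise. It does **not**
emulate haemodynamics, scanner drift, motion, spatial ROI geometry,
heritability or site effects, and its phenotype acts through a single
rank-one pattern. Passing tests therefore demonstrate the *mechanism* —
that treating dependent scans or windows as independent samples inflates
accuracy, that the inflation disappears when the fingerprint is removed,
and that cross-cohort evaluation is immune — not that any real dataset's
absolute numbers are reproduced. The published effects were measured on
restricted cohorts of thousands of subjects; this package's claims are
qualitative twins at desk scale (the whole workflow runs in about a
minute).

## Known limitations

* The identification statistic uses the per-query nearest-neighbour
  convention; sources that count unordered pairs once will report slightly
  different accuracies on the same data.
* With very short windows relative to the region count, window-level FC is
  noisy enough that the window exploit's inflation, while positive, varies
  considerably across seeds.
* The binary phenotype is a hard threshold of the continuous one, so the
  two tasks share signal structure; tasks with independent phenotypes can
  be emulated by generating two cohorts.
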