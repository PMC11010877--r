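---
title: "Core and periphery networks in longitudinal canine resting-state FC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core and periphery networks in longitudinal canine resting-state FC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in brief

`caninefc` implements an edge-wise resting-state functional-connectivity
(FC) analysis for a longitudinal working-dog cohort scanned at three
timepoints: before detection training (TP1), right after it (TP2), and
after a further maintenance period (TP3). Each dog contributes two
resting-state runs of 200 volumes at TR = 1 s per timepoint, an integrated
behavioral score (IBS: retrieve + hunt + environmental soundness, each
rated 1-5, so IBS ranges 3-15), and an eventual outcome label (successful /
non-successful detector dog).

Two dissociable networks are sought:

* **Flexible periphery** — edges whose FC *change* from TP1 to TP2
  correlates across dogs with the IBS change, whose FC significantly
  increases with training, and then holds steady through maintenance. This
  is the learning-related, experience-dependent system.
* **Stable core** — edges whose FC is stronger in eventually-successful
  dogs at every timepoint but does not change with training. Its
  pre-training strength is used to predict training success with a
  cross-validated classifier.

A connectivity-fingerprint module ranks candidate homologous regions
between two cohorts by the similarity of each region's FC profile to a
fixed set of target regions.

Because the motivating data cannot be redistributed, the package ships a
synthetic cohort generator that plants exactly this structure with known
parameters; every stage of the pipeline is validated by recovering what was
planted.

## Temporal preprocessing

The pipeline starts from ROI time series (volumes x regions) and the six
rigid-body motion parameters per run.

**Framewise displacement.** FD at frame *t* is the sum of absolute backward
differences of the three translations plus `head_radius_mm` times the
summed absolute rotation differences (arc-length conversion). The default
radius is 50 mm, the convention inherited from human work; 30 mm is a
reasonable value for a Labrador-sized head and is configurable. Frames with
FD > 0.2 mm (default `fd_threshold_mm`) are censored; their samples are
replaced by linear interpolation between the nearest retained neighbours
(edge frames held constant) so that filtering operates on a complete
series, and the censor mask is carried forward so that correlations exclude
those frames again. A run with more than half its frames censored is
rejected outright. Whether interpolation should precede or follow filtering
is genuinely open; interpolation-first is the package's choice because the
filter is global in time and would otherwise smear censored samples into
their neighbours.

**Detrending and band-pass (0.01-0.1 Hz).** The band-pass is an ideal
rectangular filter realised as an exact orthogonal projection onto the span
of the Fourier bins inside the passband, with the linear-trend direction
removed from that span. This formulation was chosen over a sequential
detrend-then-FFT-zero chain for a numerical reason: a projection is exactly
idempotent, so re-running the preprocessing chain is a no-op, bin-aligned
out-of-band components are annihilated exactly (power below 1e-10 is
asserted in the tests), and the output provably has zero mean and no trend
component. A forward-backward Butterworth filter is available behind
`filter = "butterworth"` for users who prefer a smooth transition band.

**Nuisance regression.** The six motion parameters are regressed out of
every region by least squares (an intercept is always included; residuals
are orthogonal to every confound to 1e-8). The confounds are themselves
detrended and band-limited with the same projection before regression —
standard practice (unfiltered confounds would reintroduce out-of-band
variance) which also makes the whole chain
censor → detrend → nuisance → band-pass an exact projection.

One consequence worth stating: band-passing 200 volumes at 0.01-0.1 Hz
leaves roughly 38 effective temporal degrees of freedom per run, so a
single run's correlation estimate has a null standard deviation near
1/sqrt(37), about three times that of the unfiltered series. All the power
considerations below account for this.

## FC matrices and the edge table

FC is the Pearson correlation between regions over retained frames, per
run. Values are Fisher-z transformed (`atanh`) before any averaging or
cohort statistic — the transform stabilises variance and makes t-tests on
edge values better behaved — and results can be mapped back to r where
needed. The two runs of a dog x timepoint are combined by elementwise mean
on the z scale rather than by concatenation, because censoring makes run
lengths unequal. Edges involving a zero-variance region are recorded as
missing, ignored in run averaging when the other run has them, and dropped
from cohort statistics (complete-case). All cohort statistics operate on an
edge table in a fixed lexicographic (i < j) edge order that round-trips
exactly to symmetric matrices.

## Periphery selection

For each edge, with one FC value per dog x timepoint:

1. **Tracking:** Pearson correlation across dogs between the per-dog FC
   change (TP2 - TP1, z scale) and the per-dog IBS change, tested two-sided
   at 0.05, uncorrected.
2. **Increase:** paired t-test of TP1 vs TP2 at 0.05 with a positive mean
   change. The sidedness of "significantly increased" is not determined by
   the design; the default two-sided-plus-positive-sign rule is equivalent
   to a one-sided test at 0.025, and a `one_sided = TRUE` switch reproduces
   the laxer one-sided-at-0.05 reading.
3. **Maintenance:** paired t-test of TP2 vs TP3 with p > 0.05.

An edge is selected iff all three hold. Criterion 3 is an
absence-of-evidence rule: at small n it passes by default about 95% of the
time on truly stable edges and its meaning weakens as n shrinks. It is kept
exactly as stated because it is part of the procedure being implemented,
and the confirmatory statistics — the TP3-TP1 delta-delta correlation and
the (TP2-TP1) vs (TP2-TP3) difference-of-differences test — are always
reported alongside (`strict = TRUE` makes them gate selection). No
multiple-testing correction is applied, matching the uncorrected design; a
Benjamini-Hochberg column is emitted for transparency but never gates
selection.

## Core selection, stability, and classification

**Selection.** Per edge at TP1, a Welch two-sample t-test between
successful and non-successful dogs; an edge is a core candidate when the
two-sided p is below 0.01 *and* the successful-group mean is larger. The
directional two-sided rule (null rate 0.005 under symmetry) was chosen over
a one-sided reading; it is the stricter of the two and keeps the null
calibration of the selection rate at half the two-sided level, which the
acceptance suite verifies.

**Stability.** For each selected edge, paired tests between every pair of
timepoints within each outcome group (six tests); an edge is flagged stable
iff none rejects at 0.05. Note that this flag is itself an
absence-of-evidence conjunction: for a truly drift-free edge the
probability that six correlated 5%-level tests all accept is about 0.77
(Monte Carlo), not 0.95 — the tests assert the Monte-Carlo-derived band.

**Classifier.** Ridge-penalised logistic regression (IRLS, fixed penalty
with C-equivalent 1, intercept unpenalised), features standardised with
training-set statistics only. Evaluation uses 1000 iterations of
class-stratified random 75/25 train/test splits — the
one-fold-out-of-four reading of "four-fold cross-validation with a 25% test
size"; a literal k-fold loop is a trivial variant of the same machinery.
Test-set class counts follow largest-remainder rounding, so a 13/17 cohort
always yields 3-4 successful and 4-5 non-successful test dogs. Scores
pooled over iterations give one ROC and AUC (ties receive half credit, so
the AUC equals the Mann-Whitney U statistic scaled by n1*n2); the mean of
per-iteration AUCs is reported alongside.

Two evaluation summaries, two caveats:

* **Pooled vs per-iteration AUC.** On null data the pooled AUC is
  systematically *below* 0.5 by a few percent at n = 24-30: in a finite
  cohort the training-sample association is anti-correlated with the
  held-out association, and pooling preserves each dog's consistent
  (anti-predictive) score. The mean per-iteration AUC is much closer to
  0.5 and is the summary used in the calibration checks; both are always
  reported.
* **Selection circularity.** The reproduction default
  (`mode = "full_sample"`) selects features on the full TP1 sample
  before cross-validation, which is optimistic: on pure-noise cohorts the
  circularly-selected core features score well above chance. The
  recommended `mode = "nested"` repeats the selection inside every training
  fold and is unbiased; the test suite measures the optimism gap between
  the two modes rather than hiding it.

Three feature sets are compared: the TP1 IBS alone, periphery-edge FC at
TP1, and core-edge FC at TP1 — reproducing the design where the stable core
is the strongest predictor, the flexible periphery carries weak
predictivity, and behavior is weakest.

## Fingerprint matching

A region's fingerprint is its FC to an ordered list of target regions (19
by convention); fingerprints are averaged within cohort and every cohort-B
region is ranked against each cohort-A source by cosine similarity
(Pearson-across-targets and negative Manhattan distance are options — the
similarity statistic is a declared choice, and the target identities are
configuration, since no anatomical atlas is bundled). A permutation p-value
for the top match shuffles the source profile's entries. The pipeline
demonstrates the machinery by matching the cohort's mean TP1 connectome
against a label-permuted copy of itself; no claim of anatomical homology is
made — the output is a similarity ranking.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions used everywhere in the package.

* **Cohort:** 30 dogs (13 successful / 17 non-successful), 24 with usable
  data at all three timepoints (incomplete dogs keep TP1 only), 40 regions
  (the parcellation size is not fixed by the design; 40 is a configurable
  default in the range of published dog atlas parcellations), 2 runs x 200
  volumes at TR 1 s, sex ratio 17M/13F.
* **Behavior:** latent subscores ~ N(2.8 + 0.2·successful, 0.8), a latent
  IBS gain of 2 ± 1 points from TP1 to TP2 split evenly over subscores, and
  pure noise drift (SD 0.2 per subscore) afterwards; observed subscores are
  rounded and clipped to 1-5. The successful-group advantage of 0.2 per
  subscore makes pre-training IBS weakly predictive, emulating the weak
  behavioral classifier.
* **Baseline connectome:** per dog, r_ij = c·⟨u_i, u_j⟩ with unit random
  directions u_i in R^5 and c = noise_sd·sqrt(5). This has unit diagonal,
  off-diagonal SD exactly `noise_sd` (default 0.25, a realistic
  across-subject spread for resting FC), a known smallest eigenvalue
  1 − c, and a low-rank community structure more brain-like than
  independent noise. The baseline is drawn once per dog and shared across
  timepoints, which is what gives paired tests their power.
* **Periphery edges** (default 5, disjoint): at TP2 and TP3 the edge's
  Fisher-z value gains `fc_gain` (default 0.36) plus
  `periphery_spread_sd` (default 0.30) times a mixture of the dog's
  *realized, standardized* IBS change and independent noise, weighted so
  the population correlation between the planted z change and the observed
  IBS change equals `coupling_rho` (default 0.8) exactly — coupling to the
  realized (rounded) score rather than a latent gain avoids attenuation
  from the ordinal rubric. The mean-to-spread ratio 0.36/0.30 = 1.2 makes
  the planted increase a 1.2-SD paired effect before measurement noise.
  Periphery edges also carry a small stable group effect
  (`periphery_group_d` = 0.5) so that the flexible network is weakly
  predictive at TP1, as observed empirically.
* **Core edges** (default 7, disjoint from periphery): successful dogs get
  a constant z offset of `group_effect_d * noise_sd` (default 1.5 x 0.25)
  at every timepoint — a stable group difference with no training response.
* **Positive definiteness.** Offsets are planted on the z scale
  (r = tanh(z_base + offset)), so analysis-space deltas equal the planted
  offsets exactly. When a large offset would push the smallest eigenvalue
  below tolerance, the dog's *baseline* is shrunk toward the identity (one
  factor per dog, shared across timepoints) rather than projecting the
  finished matrix: projection repair would perturb the planted edge values
  and break the closed-form coupling that the recovery tests rely on.
  Alternating-projection repair (`nearest_correlation`, tolerance 1e-8) is
  implemented, tested, and kept as a final safety net.
* **Time series:** stationary Gaussian draws with the target correlation
  (Cholesky mixing); FC analysis is correlation-only, so no temporal
  autocorrelation is planted by default, and an AR(1) switch (identical
  kernel across regions, which provably leaves the spatial correlation
  unchanged) exists for sensitivity checks.
* **Motion:** a bounded drift (FD < 0.01 mm) plus translation spikes of
  0.5 mm with per-frame probability 0.02, so the 0.2 mm censoring rule is
  exercised at realistic rates.

What the generator does **not** emulate: physiological noise and scanner
drift spectra, spatial (voxel-level) structure, breed or sex effects,
non-stationarity within runs, and any real anatomical labels. Passing the
recovery tests therefore shows that the statistical machinery is correct
and calibrated under the assumed data-generating model, not that the
biological findings would replicate.

## Power at the design conditions

With the study's sample sizes the design operates close to its limits, and
the package's simulations make that visible rather than hiding it. For the
periphery rule at n = 24 complete dogs, the joint probability that a
planted edge (coupling 0.8, 1.2-SD gain) passes all three criteria is
~0.93 — bounded above by the ~0.95 pass rate of the maintenance
(absence-of-evidence) criterion alone. For the core rule at 13 vs 17 dogs,
the directional two-sided Welch test at 0.01 against a d = 1.5 effect has
power right around 0.9 once the ~38 effective degrees of freedom per
band-passed run are accounted for; the recovered sensitivity in the
acceptance simulations sits exactly at that boundary. Raising either the
planted effects or the sample size moves both comfortably away from the
edge, but the defaults deliberately stay at the study's own conditions.

## Simulation sizes

The test suite and `scripts/acceptance.R` choose their replication counts
as a balance between Monte-Carlo precision and a desktop-scale run: null
calibration pools 36 (suite) or 12 (script) fully null cohorts of 24 dogs
(≥ 9000 edges for the rate checks); planted recovery uses 100 (suite) or 40
(script) cohorts at the design conditions with classifier comparisons on a
25- or 15-cohort subset at 400-1000 shuffle iterations; the end-to-end demo
runs a single full cohort with 1000 iterations. Every stochastic stage is
seeded, and identical configuration plus seed reproduces every output file
byte for byte.

## Known limitations

* Image-space preprocessing (slice timing, realignment, normalisation,
  smoothing) is out of scope; the pipeline starts at ROI time series.
* The FD head radius and the interpolation rule are conventions, not
  estimates; both are configurable and documented.
* `full_sample` classification is knowingly optimistic (see above);
  nested mode is the defensible estimate of predictive value.
* The maintenance and stability rules are absence-of-evidence conjunctions
  whose pass rates depend on n; the package reports their components so
  users can apply equivalence-style reasoning if they prefer.
* Fingerprint matching returns similarity rankings between configured
  label sets; it cannot establish anatomical homology.
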