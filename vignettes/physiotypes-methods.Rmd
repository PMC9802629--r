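---
title: "Deriving acute illness physiotypes from early vital signs: methods and design notes"
author: "physiotypes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving acute illness physiotypes from early vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiotypes)
```

## The problem

During the first hours of a hospital admission, clinicians triage with
little more than bedside vital signs. Unsupervised clustering of those
early measurements can reveal *physiotypes* — phenotypes defined purely by
physiologic signatures — that carry distinct risks of deterioration and
death. This package implements that analysis as a reusable pipeline:

1. **Preprocessing** — irregular raw measurements of six vitals (SBP, DBP,
   heart rate, respiratory rate, SpO2, temperature) are plausibility
   filtered, resampled to an hourly grid over the first `H = 6` hours
   (12 in sensitivity mode), imputed, and z-scored into an `N x 36`
   feature matrix.
2. **Consensus k-means** — resampled clustering builds a consensus matrix
   per candidate `k`; the CDF/delta-area rule picks the number of
   clusters; the final partition labels each encounter.
3. **Validation** — a diagonal-covariance Gaussian mixture is fit to the
   same features; agreement with the consensus partition (adjusted Rand
   index) and posterior membership strength quantify reproducibility.
4. **Prediction** — cluster centroids plus the training standardization
   form a portable model; new encounters are assigned by minimum
   Euclidean distance, letters A–D ordered by ascending systolic blood
   pressure.
5. **Acuity and outcomes** — SOFA and MEWS scores (with the `> 6` and
   `>= 5` high-acuity flags), Kaplan–Meier curves, log-rank tests,
   reverse-KM follow-up and Cox models adjusted for age, sex,
   comorbidities and SOFA band.

Because the motivating single-center EHR cohort is protected data, the
package ships a synthetic cohort generator that emulates the four
published physiologic signatures end to end, so every stage is testable.

## Preprocessing decisions

**Plausibility bounds.** Raw measurements outside HR 20–300 bpm, RR
4–80 /min, SBP 30–300 mmHg, DBP 10–200 mmHg, SpO2 50–100 %, Temp
30–43 °C are dropped as artifacts. These bounds are package defaults
(config-overridable); they are deliberately wide so that genuine
physiology is never removed.

**Exclusion.** An encounter is excluded when at least two of the six
vitals have no measurement at all inside the window. Missing only
temperature — by far the sparsest vital — keeps the encounter.

**Hourly grid and imputation.** Hour bin `h` covers minutes
`[60h, 60(h+1))`, half-open; multiple measurements in a bin are averaged.
Gaps are forward-filled from the last observed hour, leading gaps
backward-filled, and encounters with a vital entirely missing in-window
receive per-(vital, hour) training medians. Per-hour medians (rather
than one per-vital median) preserve the typical trajectory shape for
fully missing records. Every cell carries a provenance tag
(`observed`/`forward`/`backward`/`median`), and imputation never touches
the observation mask.

**Standardization.** Features are z-scored with training-cohort means and
SDs. Unscaled Euclidean distance would be dominated by blood-pressure
magnitudes (tens of mmHg against fractions of a degree Celsius), which
would contradict the standardized-feature analyses the method is built
around. Validation/test cohorts always reuse the training parameters —
refitting would silently move the centroid geometry.

## Consensus clustering

`consensusMatrix()` draws `ceiling(0.8 N)` encounters without replacement
per resample (100 resamples by default — the method's conventional
setting; the source analysis does not report its resampling parameters)
and clusters each subsample with Lloyd k-means started from k-means++
seeds, best of 5 restarts by within-cluster sum of squares. Entry
`(i, j)` is the fraction of co-clustered resamples among those where both
were drawn. The resample seed ladder is `baseSeed + r`, so any single
resample is individually replayable and the whole run is deterministic.

Model selection integrates the empirical CDF of the upper-triangular
consensus entries over `[0, 1]` to an area `A(k)`, and uses the relative
change `Delta(k) = (A(k) - A(k-1)) / A(k-1)` (with `Delta(2) = A(2)`).
The selected `k` is the largest with `Delta(k) > 0.10`; the strict
inequality keeps the smaller, more parsimonious `k` on boundary ties, and
the fallback is `k = 2`. The threshold formalizes the usual visual
"elbow" reading of delta-area plots; `k` is scanned over 2–8.

The final partition comes from full-data k-means at the selected `k`
rather than from re-clustering the consensus matrix: the downstream
prediction artifact is a set of k-means centroids, which presumes a
k-means partition. Within-cluster mean pairwise consensus is reported as
a stability diagnostic (singletons report 1 by convention, with a
warning).

## Gaussian-mixture validation

The reproducibility check fits a Gaussian mixture by EM with diagonal
covariances: with 36 features and cohorts in the hundreds-to-thousands,
full 36x36 covariances per component are unstable, and the diagonal
model is the standard choice at this dimension. Ten random starts are
run and the best log-likelihood kept; component variances are floored at
`1e-6` of the feature variance; the per-iteration log-likelihood trace is
stored and asserted non-decreasing in the tests. BIC is
`-2 logL + p ln N` with `p = (k-1) + 2kF`. Membership quality summarizes
each encounter's maximum posterior; assignments with maximum posterior in
`[0.45, 0.55]` are flagged as marginal.

## The synthetic cohort generator

The generator defines the study conditions for every recovery test; its
defaults are fixed once and are not tuned against test outcomes.

* **Templates.** Four mean trajectories over six hours encode the
  signatures: A — persistent hypotension (SBP ≈ 95 mmHg) without a
  compensatory heart-rate rise, mild hypothermia; B — moderate
  hypotension with tachycardia (HR ≈ 110), tachypnea (RR ≈ 26),
  hypoxemia (SpO2 ≈ 90 %) and fever; C — normotensive, minimal
  derangement; D — severe hypertension (SBP > 160 mmHg at every hour).
  The published figures show only distributions, so the exact hourly
  means are generator choices chosen to be clinically typical of each
  signature; they are documented in `makeDefaultTemplates()` and are not
  claims about the real cohort. A `separation` multiplier interpolates
  between a common reference trajectory (`separation = 0`, no signal)
  and the full signatures (`separation = 1`, default).
* **Mixing and outcomes.** Phenotype proportions default to
  (0.31, 0.23, 0.31, 0.15) and 3-year mortality to
  (0.17, 0.25, 0.16, 0.20) in A–D order — the published cohort-level
  rates, used here as generator parameters. Event times are exponential
  with rate `-ln(1 - p3y)/1095` per day, so the cumulative event
  fraction at three years equals `p3y` exactly; administrative censoring
  at 1570 days makes the reverse-KM median follow-up about 4.3 years.
  The published per-phenotype 30-day rates are stored on the templates
  as descriptive parameters but the exponential model is not piecewise
  recalibrated to them.
* **Sampling process.** Within an encounter, each vital's latent hourly
  value follows an AR(1) process (lag-1 correlation 0.6, stationary SD
  per vital) around the template trajectory — autocorrelated noise makes
  forward-fill imputation realistic, which white noise would not. A
  non-missing hour holds `max(1, Poisson(1.5))` raw measurements at
  uniform integer minute offsets, exercising the in-bin averaging path.
  An hour is missing entirely with probability 0.10 per vital, 0.45 for
  temperature (the high-missingness vital). With probability 0.01 a
  measurement is replaced by an out-of-range artifact to exercise the
  plausibility filter. SpO2 noise is symmetric around the template mean,
  so a small tail above 100 % can be generated and is trimmed by the
  filter like any other artifact.
* **What it does not emulate.** Real vitals have measurement-frequency
  informative of acuity, device-specific error structure, within-hour
  trends, charting duplicates and transfers; none of these are modeled.
  Passing recovery tests therefore demonstrates the pipeline's
  correctness and its behavior under realistic noise, missingness and
  class imbalance — not clinical performance on real EHR data.

## Acuity scoring

The SOFA and MEWS tables ship as a JSON data file
(`inst/extdata/acuity_tables.json`) encoded from the original score
publications, since the source analysis prints neither; scoring code
reads the table, so institutional variants can be swapped in. Decisions:

* Missing components score 0 ("normal") and are tagged — the only policy
  that never inflates acuity.
* The renal subscore is creatinine-only (no urine output in the data
  model).
* A binary vasopressor flag scores the lowest pressor tier (2) of the
  cardiovascular subscore; dose tiers are present in the table file for
  data that carry them.
* MEWS worst-in-window is computed by scoring *every* in-window
  measurement and keeping the maximum points per component, so a vital
  that is both too low and too high during the window flags correctly.
* Flags follow the published thresholds: high acuity is SOFA total > 6
  and MEWS total ≥ 5.

## Outcomes

Kaplan–Meier estimation, the log-rank test and Cox regression delegate to
the `survival` package (Efron tie handling, Wald 95% intervals), with
physiotype C — the favorable-outcome phenotype — as the reference level
and Bonferroni adjustment using the family of within-row comparisons
against the reference (family size 3). The reverse-KM median follow-up
uses the convention that the median is the first time the follow-up curve
falls *strictly* below 0.5; a curve that only touches 0.5 continues (so
50/50 censoring at days 100/200 gives a median of 200), and a curve that
never crosses is reported open-ended.

## Characterization

Pairwise standardized mean differences re-standardize each feature on the
pooled pair of phenotypes (not globally), matching the per-pair scaling
of the published comparisons; a group mean of +1 is one pooled SD above
the pair. The self-organizing map uses online Kohonen updates on an
`8 x 8` grid (20 epochs, learning rate 0.5 → 0.01, Gaussian neighborhood
with radius `G/2 → 0.5`; updates apply within the shrinking radius, so
late training refines only the winning node). The 2-D embedding is a
principal-component projection: the contract is only that separable
phenotypes stay visually separated, and a deterministic projection keeps
runs reproducible; a stochastic neighbor embedding can be substituted
behind the same interface.

## Numerical conventions and degenerate inputs

* k-means: Lloyd iterations capped at 100; `k = 1` returns the trivial
  partition; `k > N` errors.
* Consensus pairs never co-sampled get consensus 0 with a warning
  (practically impossible at 100 resamples and fraction 0.8).
* Zero-variance features abort standardization fitting (degenerate
  input); constant features in an SMD pair contribute zero difference.
* Prediction distance ties break toward the earlier letter, with a
  `1e-9` relative tolerance so exact geometric ties are not decided by
  floating-point noise.
* The model artifact serializes doubles at 17 significant digits, which
  reproduces IEEE doubles exactly; round-tripped models predict
  bit-identically.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish quickly while
leaving comfortable statistical margins: consensus selection and mixture
validation on an `n = 600` cohort at 100 resamples over `k = 2..8`;
label recovery at `n = 400` (adjusted Rand index ≥ 0.90); Cox log-HR
bias below 0.05 at `n = 2000` over 100 replicates with the published
hazard ladder (1.1, 1.4, 1.8) as simulation truth; log-rank type-I error
over 1000 null replicates of `n = 100`; and brute-force oracle
equivalences at `N ≤ 8`.

## Known limitations

* The pipeline clusters fixed-window summaries; it does not model
  temporal ordering beyond the hour index.
* Exponential survival is a deliberate simplification; hazard shapes in
  real cohorts are not exponential, and the Cox recovery results speak
  to estimator correctness, not to fit of that model.
* The delta-area threshold (0.10) formalizes a visual rule; cohorts with
  genuinely hierarchical structure can be sensitive to it, which is why
  the full area/delta trace is kept in the `ConsensusResult`.
* Charlson-type comorbidity indices are accepted as inputs, never
  computed.
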