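# physiotypes

Discovery, validation and characterization of **acute illness
physiotypes** — patient phenotypes defined purely by vital-sign
physiology in the first hours of hospital admission.

Clinicians triage new admissions with little more than bedside vitals.
Clustering those early measurements reveals a small number of
physiologic signatures (persistent hypotension without tachycardia;
tachycardia–tachypnea–hypoxemia; minimal derangement; severe
hypertension) with distinct short- and long-term outcomes. This package
implements the full analysis for biostatisticians and clinical
informaticians working with EHR vital-sign tables:

* **Preprocessing**: plausibility filtering, the missing-vitals
  exclusion rule, hourly resampling (half-open bins, in-bin means),
  forward/backward/median imputation and training-cohort z-scoring into
  an `N x 36` feature matrix (6 vitals x 6 hours).
* **Consensus k-means**: for each `k` in 2..8, cluster 100 random 80%
  subsamples and record how often each pair of encounters lands
  together: the consensus matrix `M_k` with entries
  `M_k(i,j) = #(co-clustered) / #(co-sampled)`. The empirical CDF of the
  pairwise consensus values is integrated to an area `A(k)`, and the
  relative change `Δ(k) = (A(k) − A(k−1))/A(k−1)` selects the number of
  clusters (largest `k` with `Δ(k) > 0.1`).
* **Validation**: diagonal-covariance Gaussian mixture (EM, 10 starts,
  BIC = −2 logL + p ln N), posterior membership quality, adjusted Rand
  index between partitions.
* **Prediction**: a portable model of labeled centroids (letters A–D by
  ascending systolic blood pressure) plus the training standardization;
  new encounters are assigned by minimum Euclidean distance.
* **Acuity**: SOFA and MEWS from shipped lookup tables, with the
  high-acuity flags SOFA > 6 and MEWS ≥ 5.
* **Outcomes**: Kaplan–Meier curves, log-rank tests, reverse-KM median
  follow-up and Cox proportional-hazards models (Efron ties) with
  physiotype C as the reference.
* **Synthetic cohorts**: a generator emulating the four signatures —
  AR(1) vital trajectories, irregular sampling, vital-specific
  missingness, outlier artifacts and phenotype-linked exponential
  survival — so the whole pipeline is testable without protected data.

## Worked example

```r
library(physiotypes)

templates <- makeDefaultTemplates()               # the four signatures
cohort <- generateCohort(templates, n = 300, seed = 1)
pp <- preprocessCohort(cohort$vitals, cohort$encounters)

res <- consensusCluster(featureMatrix(pp$features), kRange = 2:6,
                        scheme = resampleScheme(50, 0.8, 1))
res
#> ConsensusResult: k in 2..6, selected k = 4 (N = 300)
#>   CDF areas:   k=2 0.337  k=3 0.522  k=4 0.728  k=5 0.782  k=6 0.817
#>   delta area:  k=2 0.337  k=3 0.549  k=4 0.395  k=5 0.075  k=6 0.045
```

The area under the consensus CDF keeps growing while added clusters
split real structure (`Δ(3) = 0.55`, `Δ(4) = 0.40`) and flattens once
they only split noise (`Δ(5) = 0.075 < 0.1`), so four clusters are
selected — the expected answer on a four-template cohort.

```r
model <- deriveModel(pp$features, finalLabels(res))
pred <- predictPhysiotype(model, pp$features)
truth <- SummarizedExperiment::colData(pp$features)$true_label
table(predicted = pred$label, truth = truth)
#>          truth
#> predicted   A   B   C   D
#>         A  92   0   1   0
#>         B   0  64   0   0
#>         C   0   0 101   0
#>         D   0   0   0  42
```

The recovered letters match the generating phenotypes almost perfectly
(one borderline encounter); letters are assigned by ascending systolic
blood pressure, so "A" is the hypotensive and "D" the hypertensive
signature.

```r
surv <- survivalByPhysiotype(data.frame(
  time = cohort$encounters$time_days,
  event = cohort$encounters$event,
  physiotype = truth))
surv$logrank
#> $chisq
#> [1] 7.676021
#> $df
#> [1] 3
#> $p
#> [1] 0.05320411
```

At `n = 300` the phenotype-linked mortality differences (3-year
mortality 0.16–0.25 across groups) are borderline-detectable, as the
log-rank p-value shows; larger cohorts separate the survival curves
clearly.

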