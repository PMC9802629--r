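# Shared fixtures and independent oracles used across test files.

# small preprocessed synthetic cohort (features + truth labels)
makeFixtureCohort <- function(n = 150, seed = 42, separation = 1,
                              hours = 6) {
  tpl <- makeDefaultTemplates(hours = hours, separation = separation)
  coh <- generateCohort(tpl, n = n, seed = seed)
  pp <- suppressMessages(preprocessCohort(coh$vitals, coh$encounters,
                                          config = runConfig(windowHours = hours)))
  list(templates = tpl, cohort = coh, pp = pp,
       X = featureMatrix(pp$features),
       truth = SummarizedExperiment::colData(pp$features)$true_label)
}

# brute-force minimum WCSS over all 2-partitions of the rows of X
bruteForceWcss2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.integer(intToBits(mask))[1:n]
    wcss <- 0
    for (gg in 0:1) {
      sub <- X[g == gg, , drop = FALSE]
      wcss <- wcss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    if (wcss < best) best <- wcss
  }
  best
}

# independent product-limit estimator by direct risk-set enumeration
handKm <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ts) {
    atRisk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / atRisk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# independent log-rank chi-square (two groups) by risk-set enumeration
handLogrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n1 <- sum(time >= t & group == g[1])
    n2 <- sum(time >= t & group == g[2])
    d1 <- sum(time == t & event == 1 & group == g[1])
    d2 <- sum(time == t & event == 1 & group == g[2])
    n <- n1 + n2; d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# independent re-encoding of the SOFA subscores (if/else chains, no
# shared code with the band tables)
oracleSofa <- function(pf, plt, bili, map, vaso, gcs, crea) {
  resp <- if (pf < 100) 4 else if (pf < 200) 3 else if (pf < 300) 2 else
    if (pf < 400) 1 else 0
  coag <- if (plt < 20) 4 else if (plt < 50) 3 else if (plt < 100) 2 else
    if (plt < 150) 1 else 0
  liver <- if (bili >= 12) 4 else if (bili >= 6) 3 else if (bili >= 2) 2 else
    if (bili >= 1.2) 1 else 0
  cardio <- if (vaso > 0) 2 else if (map < 70) 1 else 0
  neuro <- if (gcs < 6) 4 else if (gcs < 10) 3 else if (gcs < 13) 2 else
    if (gcs < 15) 1 else 0
  renal <- if (crea >= 5) 4 else if (crea >= 3.5) 3 else if (crea >= 2) 2 else
    if (crea >= 1.2) 1 else 0
  resp + coag + liver + cardio + neuro + renal
}

# independent re-encoding of MEWS
oracleMews <- function(sbp, hr, rr, temp, avpu) {
  s <- if (sbp <= 70) 3 else if (sbp <= 80) 2 else if (sbp <= 100) 1 else
    if (sbp < 200) 0 else 2
  h <- if (hr <= 40) 2 else if (hr <= 50) 1 else if (hr <= 100) 0 else
    if (hr <= 110) 1 else if (hr < 130) 2 else 3
  r <- if (rr < 9) 2 else if (rr < 15) 0 else if (rr < 21) 1 else
    if (rr < 30) 2 else 3
  t <- if (temp < 35) 2 else if (temp < 38.5) 0 else 2
  a <- c(Alert = 0, Voice = 1, Pain = 2, Unresponsive = 3)[avpu]
  s + h + r + t + unname(a)
}
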