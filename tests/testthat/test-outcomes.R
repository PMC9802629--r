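test_that("Kaplan-Meier matches the hand product-limit oracle", {
  km <- kmEstimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))

  allCens <- kmEstimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(allCens$surv == 1))

  time <- c(2, 3, 3, 5, 8, 9)
  event <- c(1, 1, 0, 1, 0, 1)
  km2 <- kmEstimate(time, event)
  oracle <- handKm(time, event)
  got <- km2[km2$n_event > 0, c("time", "surv")]
  rownames(got) <- NULL
  expect_equal(got, oracle, tolerance = 1e-12)

  # S(0) = 1 and non-increasing, right-continuous step function
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(km2$surv[1] <= 1)

  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank matches risk-set enumeration and its conventions", {
  t1 <- c(1, 3, 5, 7); t2 <- c(2, 4, 6, 8)
  time <- c(t1, t2); event <- rep(1, 8)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrankTest(time, event, group)
  expect_equal(lr$df, 1)
  expect_equal(lr$chisq, handLogrank2(time, event, group),
               tolerance = 1e-9)

  # identical groups: statistic 0
  lr0 <- logrankTest(c(t1, t1), rep(1, 8), group)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)

  # relabeling the groups leaves the statistic unchanged
  lrSwap <- logrankTest(time, event, rep(c("b", "a"), each = 4))
  expect_equal(lr$chisq, lrSwap$chisq)

  expect_warning(lrNull <- logrankTest(1:6, rep(0, 6),
                                       rep(c("a", "b"), 3)), "no events")
  expect_equal(lrNull$chisq, 0)
  expect_equal(lrNull$p, 1)

  expect_error(logrankTest(1:4, rep(1, 4), rep("a", 4)), "at least 2")
})

test_that("reverse Kaplan-Meier reports median follow-up", {
  # everyone censored at 100 days
  expect_equal(reverseKmFollowup(rep(100, 8), rep(0, 8)), 100)

  # all events: the follow-up curve never drops; open-ended
  r <- reverseKmFollowup(c(10, 20, 30), c(1, 1, 1))
  expect_true(is.na(r))
  expect_true(attr(r, "openEnded"))

  # 50/50 censored at 100 and 200 days: the curve sits exactly at 0.5
  # after day 100 and only falls below at 200
  expect_equal(reverseKmFollowup(c(100, 100, 200, 200), rep(0, 4)), 200)

  # the generator's default horizon yields ~4.3 years of follow-up
  coh <- generateCohort(makeDefaultTemplates(), 800, seed = 41)
  med <- reverseKmFollowup(coh$encounters$time_days,
                           coh$encounters$event)
  expect_equal(med / 365.25, 4.3, tolerance = 0.01)
})

test_that("Cox fits recover null and reference-swap symmetries", {
  set.seed(6)
  n <- 500
  d <- data.frame(
    time = rexp(n, 0.01), event = rbinom(n, 1, 0.8),
    physiotype = sample(c("B", "C"), n, TRUE)
  )
  fit <- coxFit(d)
  expect_lt(abs(log(fit$hr[1])), 0.25)  # null covariate, modest n

  # swapping the reference inverts the hazard ratio
  fit2 <- coxFit(d, reference = "B")
  expect_equal(log(fit$hr[1]), -log(fit2$hr[1]), tolerance = 1e-6)
  expect_true(all(fit$lower <= fit$hr & fit$hr <= fit$upper))

  expect_error(coxFit(d[, 1:2]), "physiotype")
})

test_that("Cox recovers the simulated physiotype hazard ladder", {
  # exponential groups with true HRs 1.1, 1.4, 1.8 vs reference C
  hrTrue <- c(A = 1.1, B = 1.8, D = 1.4)
  set.seed(7)
  n <- 2000
  lab <- sample(c("A", "B", "C", "D"), n, TRUE,
                prob = c(0.31, 0.23, 0.31, 0.15))
  base <- 0.0005
  rate <- base * ifelse(lab == "C", 1, hrTrue[lab])
  t <- rexp(n, rate)
  d <- data.frame(time = pmin(t, 1095), event = as.integer(t <= 1095),
                  physiotype = lab)
  fit <- coxFit(d)
  est <- setNames(log(fit$hr), sub("physiotype", "", fit$term))
  for (g in names(hrTrue)) {
    expect_lt(abs(est[g] - log(hrTrue[g])), 0.2)
  }
})

test_that("group comparison tests match hand-computed statistics", {
  g <- rep(c("x", "y"), each = 10)

  # 2x2 table (10,0 / 0,10): chi-square 20 without continuity correction
  v <- rep(c("p", "q"), each = 10)
  r <- groupCompare(v, g, "categorical")
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)

  # identical categorical distributions: statistic 0
  v0 <- rep(c("p", "q"), 10)
  expect_equal(groupCompare(v0, g, "categorical")$statistic, 0)

  # Kruskal-Wallis on identical groups: H = 0
  x <- rep(c(1, 2, 3, 4, 5), 4)
  expect_equal(groupCompare(x, g, "continuous-rank")$statistic, 0)

  # ANOVA F agrees with the classical two-group t^2 relation
  set.seed(8)
  y <- rnorm(20)
  fr <- groupCompare(y, g, "continuous-normal")
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(fr$statistic, unname(tt$statistic^2), tolerance = 1e-9)

  expect_error(groupCompare(v, rep("x", 20)), "at least 2")
})

test_that("Bonferroni adjustment caps at 1 and never shrinks", {
  expect_equal(bonferroniAdjust(0.01, 3), 0.03)
  expect_equal(bonferroniAdjust(0.5, 3), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroniAdjust(0.2, 1), 0.2)
  set.seed(9)
  p <- runif(10)
  adj <- bonferroniAdjust(p, 12)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bonferroniAdjust(1.2, 3), "0, 1")
  expect_error(bonferroniAdjust(runif(5), 3), "familySize")
})

test_that("physiotype survival summary produces curves and a log-rank test", {
  coh <- generateCohort(makeDefaultTemplates(), 600, seed = 43)
  d <- data.frame(time = coh$encounters$time_days,
                  event = coh$encounters$event,
                  physiotype = coh$encounters$true_label)
  s <- survivalByPhysiotype(d)
  expect_named(s$curves, c("A", "B", "C", "D"))
  expect_equal(s$logrank$df, 3)
  for (cv in s$curves) expect_true(all(diff(cv$surv) <= 1e-12))
})
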