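mkVitals <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(encounter_id = r[[1]], vital = r[[2]],
               offset_minutes = as.numeric(r[[3]]),
               value = as.numeric(r[[4]]))))
}

test_that("plausibility filtering drops out-of-range measurements", {
  v <- mkVitals(list("E1", "HR", 0, 30), list("E1", "HR", 10, 400),
                list("E1", "HR", 20, 72))
  out <- suppressMessages(filterOutliers(v))
  expect_equal(out$value, c(30, 72))

  ok <- mkVitals(list("E1", "HR", 0, 60), list("E1", "HR", 10, 80))
  expect_equal(filterOutliers(ok), ok)  # in-range data pass unchanged

  sp <- mkVitals(list("E1", "SpO2", 0, 101))
  expect_equal(nrow(suppressMessages(filterOutliers(sp))), 0)
})

test_that("exclusion rule requires at least two fully missing vitals", {
  base <- do.call(rbind, lapply(setdiff(vitalNames(), "Temp"), function(v)
    mkVitals(list("E1", v, 30, 100))))
  # missing only temperature: kept
  ex <- excludeEncounters(base, "E1")
  expect_equal(ex$kept, "E1")

  # missing temperature and RR: excluded (boundary at two)
  two <- base[base$vital != "RR", ]
  ex2 <- excludeEncounters(two, "E1")
  expect_equal(ex2$excluded, "E1")

  # all six present: kept
  all6 <- rbind(base, mkVitals(list("E1", "Temp", 30, 37)))
  expect_equal(excludeEncounters(all6, "E1")$kept, "E1")

  # measurements outside the window do not count
  late <- transform(base, offset_minutes = 400)
  expect_equal(excludeEncounters(late, "E1", windowHours = 6)$excluded, "E1")

  # encounter with no rows at all is excluded
  ex3 <- excludeEncounters(base, c("E1", "E2"))
  expect_equal(ex3$excluded, "E2")
})

test_that("exclusion is monotone: adding measurements never excludes", {
  set.seed(1)
  for (rep in 1:20) {
    nv <- sample(0:6, 1)
    vits <- sample(vitalNames(), nv)
    v <- if (nv > 0)
      do.call(rbind, lapply(vits, function(x)
        mkVitals(list("E1", x, sample(0:300, 1), 90))))
    else mkVitals(list("E1", "HR", 500, 90))[0, ]
    keptBefore <- "E1" %in% excludeEncounters(v, "E1")$kept
    extra <- rbind(v, mkVitals(list("E1", sample(vitalNames(), 1), 10, 90)))
    keptAfter <- "E1" %in% excludeEncounters(extra, "E1")$kept
    if (keptBefore) expect_true(keptAfter)
  }
})

test_that("hourly resampling uses half-open bins and in-bin means", {
  rs <- resampleHourly(c(10, 50), c(80, 90), 6)
  expect_equal(rs$values[1], 85)

  rs2 <- resampleHourly(60, 100, 6)  # minute 60 belongs to hour 2
  expect_true(is.na(rs2$values[1]))
  expect_equal(rs2$values[2], 100)

  rs3 <- resampleHourly(numeric(0), numeric(0), 6)
  expect_true(all(!rs3$mask) && all(is.na(rs3$values)))
})

test_that("imputation fills forward, then backward, then medians", {
  H <- 6
  vals <- matrix(NA_real_, 6, H,
                 dimnames = list(vitalNames(), paste0("h", 1:H)))
  mask <- matrix(FALSE, 6, H, dimnames = dimnames(vals))
  vals["HR", c(2, 5)] <- c(100, 110); mask["HR", c(2, 5)] <- TRUE
  vals["SBP", ] <- 120; mask["SBP", ] <- TRUE
  src <- matrix("", 6, H, dimnames = dimnames(vals))
  src[mask] <- "observed"
  g <- new("VitalGrid", encounterId = "E1", values = vals,
           observedMask = mask, source = src)
  med <- matrix(rep(c(120, 70, 98, 98, 97, 37), H), 6, H,
                dimnames = dimnames(vals))
  med["HR", ] <- c(98, 98, 97, 97, 97, 97)

  gi <- imputeGrid(g, med)
  expect_equal(unname(gi@values["HR", ]), c(100, 100, 100, 100, 110, 110))
  expect_equal(unname(gi@source["HR", ]),
               c("backward", "observed", "forward", "forward",
                 "observed", "forward"))
  # fully observed row unchanged
  expect_equal(unname(gi@values["SBP", ]), rep(120, H))
  expect_equal(unname(gi@source["SBP", ]), rep("observed", H))
  # fully missing row takes the per-hour training medians
  expect_equal(unname(gi@values["Temp", ]), rep(37, H))
  expect_true(all(gi@source["Temp", ] == "median"))
  # the mask is never altered
  expect_identical(gi@observedMask, g@observedMask)

  # idempotence on a complete grid
  gii <- imputeGrid(gi, med)
  expect_identical(gii@values, gi@values)

  badMed <- med; badMed["RR", 3] <- NA
  expect_error(imputeGrid(g, badMed), "complete")
})

test_that("feature construction yields vital-major z-scored features", {
  fx <- makeFixtureCohort(n = 120, seed = 8)
  X <- fx$X
  expect_equal(ncol(X), 36)
  expect_equal(colnames(X)[1:7],
               c(paste0("SBP.h", 1:6), "DBP.h1"))
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-9))

  # standardization inverts exactly
  st <- standardization(fx$pp$features)
  raw <- destandardize(X, st)
  Z2 <- sweep(sweep(raw, 2, st$mean), 2, st$sd, `/`)
  expect_lt(max(abs(Z2 - X)), 1e-9)

  # sensitivity mode: dropping temperature leaves 5 x 6 = 30 features
  cfg5 <- runConfig(includedVitals = setdiff(vitalNames(), "Temp"))
  pp5 <- suppressMessages(preprocessCohort(fx$cohort$vitals,
                                           fx$cohort$encounters,
                                           config = cfg5))
  expect_equal(ncol(featureMatrix(pp5$features)), 30)

  # degenerate input: constant feature is an error in fitting mode
  g <- fx$pp$grids[1:3]
  for (i in seq_along(g)) g[[i]]@values["Temp", ] <- 37
  expect_error(buildFeatures(g), "zero-variance")
})

test_that("training standardization transfers to a later cohort", {
  fx <- makeFixtureCohort(n = 120, seed = 8)
  coh2 <- generateCohort(fx$templates, 60, seed = 99)
  pp2 <- suppressMessages(preprocessCohort(
    coh2$vitals, coh2$encounters,
    standardize = fx$pp$standardization, medians = fx$pp$medians))
  expect_identical(standardization(pp2$features), fx$pp$standardization)
  # projected features are not re-centered on the new cohort
  expect_gt(max(abs(colMeans(featureMatrix(pp2$features)))), 1e-6)
})
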