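normalInputs <- function(n = 1) {
  data.frame(
    pao2_fio2 = rep(450, n), platelets = 250, bilirubin = 0.5,
    map_mmHg = 80, vasopressor = 0, gcs = 15, creatinine = 0.8
  )
}

test_that("SOFA scores normal physiology as zero and flags totals over 6", {
  r <- computeSofa(normalInputs())
  expect_equal(r$sofa_total, 0)
  expect_false(r$sofa_gt6)

  # a single worst component: GCS 3 gives the neurologic maximum
  gcs3 <- transform(normalInputs(), gcs = 3)
  r2 <- computeSofa(gcs3)
  expect_equal(r2$sofa_neurologic, 4)
  expect_equal(r2$sofa_total, 4)

  # total 7 crosses the high-acuity threshold; 6 does not
  sick <- transform(normalInputs(), pao2_fio2 = 150, platelets = 90,
                    creatinine = 2.5)  # 3 + 2 + 2 = 7
  r3 <- computeSofa(sick)
  expect_equal(r3$sofa_total, 7)
  expect_true(r3$sofa_gt6)
  sick6 <- transform(sick, creatinine = 1.5)  # 3 + 2 + 1 = 6
  expect_false(computeSofa(sick6)$sofa_gt6)
})

test_that("missing SOFA components default to normal and are tagged", {
  partial <- data.frame(gcs = 12, creatinine = 2.1)
  r <- computeSofa(partial)
  expect_equal(r$sofa_total, 2 + 2)
  expect_match(r$sofa_missing, "respiratory")
  expect_match(r$sofa_missing, "cardiovascular")

  expect_error(computeSofa(data.frame(pao2_fio2 = NA_real_)),
               "at least one")

  # a vasopressor flag scores the cardiovascular system even without MAP
  vaso <- data.frame(gcs = 15, vasopressor = 1)
  expect_equal(computeSofa(vaso)$sofa_cardiovascular, 2)
})

test_that("MEWS scores normal vitals as zero with the >= 5 flag boundary", {
  r <- computeMews(data.frame(sbp = 120, hr = 75, rr = 14, temp_c = 36.8,
                              avpu = "Alert"))
  expect_equal(r$mews_total, 0)
  expect_false(r$mews_ge5)

  # total exactly 5 flags; 4 does not
  r5 <- computeMews(data.frame(sbp = 85, hr = 112, rr = 22, temp_c = 37))
  expect_equal(r5$mews_total, 1 + 2 + 2)
  expect_true(r5$mews_ge5)
  r4 <- computeMews(data.frame(sbp = 85, hr = 105, rr = 22, temp_c = 37))
  expect_equal(r4$mews_total, 4)
  expect_false(r4$mews_ge5)

  expect_error(computeMews(data.frame(sbp = 120, hr = 80)), "requires rr")
  expect_error(computeMews(data.frame(sbp = 120, hr = 80, rr = 14,
                                      avpu = "Sleepy")), "unknown AVPU")
})

test_that("both scores match an independent re-encoding on random inputs", {
  set.seed(11)
  for (i in 1:50) {
    pf <- runif(1, 40, 500); plt <- runif(1, 5, 400)
    bili <- runif(1, 0.1, 15); map <- runif(1, 40, 110)
    vaso <- rbinom(1, 1, 0.3); gcs <- sample(3:15, 1)
    crea <- runif(1, 0.3, 7)
    got <- computeSofa(data.frame(pao2_fio2 = pf, platelets = plt,
                                  bilirubin = bili, map_mmHg = map,
                                  vasopressor = vaso, gcs = gcs,
                                  creatinine = crea))
    expect_equal(got$sofa_total,
                 oracleSofa(pf, plt, bili, map, vaso, gcs, crea))

    sbp <- sample(40:220, 1); hr <- sample(30:160, 1)
    rr <- sample(5:40, 1); temp <- round(runif(1, 33, 40.5), 1)
    avpu <- sample(c("Alert", "Voice", "Pain", "Unresponsive"), 1)
    gotM <- computeMews(data.frame(sbp = sbp, hr = hr, rr = rr,
                                   temp_c = temp, avpu = avpu))
    expect_equal(gotM$mews_total, oracleMews(sbp, hr, rr, temp, avpu))
  }
})

test_that("worsening any single component never decreases the totals", {
  base <- normalInputs()
  worse <- list(pao2_fio2 = c(450, 350, 250, 150, 50),
                platelets = c(250, 140, 90, 40, 15),
                bilirubin = c(0.5, 1.5, 3, 8, 13),
                map_mmHg = c(80, 65),
                gcs = c(15, 14, 11, 8, 4),
                creatinine = c(0.8, 1.5, 2.5, 4, 6))
  for (comp in names(worse)) {
    totals <- vapply(worse[[comp]], function(x) {
      inp <- base; inp[[comp]] <- x
      computeSofa(inp)$sofa_total
    }, 0)
    expect_true(all(diff(totals) >= 0))
  }
  # every subscore stays within 0..4
  set.seed(2)
  for (i in 1:25) {
    r <- computeSofa(data.frame(
      pao2_fio2 = runif(1, 40, 500), platelets = runif(1, 5, 400),
      bilirubin = runif(1, 0.1, 15), map_mmHg = runif(1, 40, 110),
      vasopressor = rbinom(1, 1, 0.5), gcs = sample(3:15, 1),
      creatinine = runif(1, 0.3, 7)))
    sub <- unlist(r[paste0("sofa_", c("respiratory", "coagulation",
                                      "liver", "cardiovascular",
                                      "neurologic", "renal"))])
    expect_true(all(sub >= 0 & sub <= 4))
    expect_equal(r$sofa_total, sum(sub))
    expect_equal(r$sofa_gt6, r$sofa_total >= 7)
  }
})

test_that("cohort-level scoring takes the worst measurement per component", {
  enc <- normalInputs()
  enc$encounter_id <- "E1"
  # heart rate both bradycardic and normal within the window: the
  # bradycardic reading (2 points) must win
  vit <- data.frame(
    encounter_id = "E1",
    vital = c("HR", "HR", "SBP", "RR", "Temp"),
    offset_minutes = c(10, 200, 30, 30, 30),
    value = c(38, 80, 120, 14, 36.8)
  )
  r <- computeAcuity(enc, vit)
  expect_equal(r$mews_hr, 2)
  expect_equal(r$mews_total, 2)
  # measurements beyond the window are ignored
  vit2 <- vit; vit2$offset_minutes[1] <- 25 * 60
  r2 <- computeAcuity(enc, vit2)
  expect_equal(r2$mews_hr, 0)
})
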