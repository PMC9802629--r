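# Synthetic EHR cohort generator.
#
# Emulates four latent physiologic signatures over the first hours of
# admission: A, persistent hypotension without a compensatory heart-rate
# rise; B, hypotension with tachycardia, tachypnea, hypoxemia and fever;
# C, minimal derangement; D, severe hypertension. Labels follow ascending
# systolic blood pressure. Mean trajectories are generator choices (the
# source cohort is not public); group proportions and mortality
# parameters are set to the published cohort-level rates so downstream
# recovery tests run under realistic class balance and event rates.

.templateShapes <- function() {
  list(
    A = rbind(
      SBP = c(97, 95, 94, 95, 96, 97),
      DBP = c(56, 55, 54, 55, 56, 57),
      HR = c(86, 85, 85, 84, 84, 84),
      RR = c(17, 17, 17, 17, 17, 17),
      SpO2 = c(96.5, 96.5, 96.5, 96.5, 96.5, 96.5),
      Temp = c(36.3, 36.2, 36.2, 36.2, 36.3, 36.3)
    ),
    B = rbind(
      SBP = c(107, 105, 104, 104, 105, 106),
      DBP = c(62, 60, 59, 59, 60, 61),
      HR = c(112, 114, 113, 111, 109, 107),
      RR = c(26, 27, 27, 26, 25, 24),
      SpO2 = c(91, 90, 90, 91, 91, 92),
      Temp = c(37.8, 37.9, 38.0, 38.0, 37.9, 37.8)
    ),
    C = rbind(
      SBP = c(124, 123, 122, 122, 121, 121),
      DBP = c(72, 71, 70, 70, 70, 70),
      HR = c(86, 84, 83, 82, 81, 80),
      RR = c(18, 18, 17, 17, 17, 17),
      SpO2 = c(96.5, 96.5, 96.5, 96.5, 96.5, 96.5),
      Temp = c(36.8, 36.8, 36.8, 36.8, 36.8, 36.8)
    ),
    D = rbind(
      SBP = c(178, 176, 174, 172, 170, 168),
      DBP = c(97, 96, 95, 94, 93, 92),
      HR = c(90, 89, 88, 87, 86, 86),
      RR = c(19, 19, 18, 18, 18, 18),
      SpO2 = c(96, 96, 96, 96, 96, 96),
      Temp = c(36.8, 36.8, 36.8, 36.8, 36.8, 36.8)
    )
  )
}

# stretch/truncate a 6-hour shape to H hours (steady state after hour 6)
.shapeToHours <- function(m, hours) {
  if (hours <= 6) return(m[, seq_len(hours), drop = FALSE])
  cbind(m, m[, rep(6, hours - 6), drop = FALSE])
}

#' Default phenotype templates for the four physiologic signatures
#'
#' Builds the four generator templates. The mean trajectories interpolate
#' between a common reference trajectory and the signature-specific
#' trajectories: with \code{separation = 0} all four templates share the
#' reference (a degenerate no-signal cohort), with \code{separation = 1}
#' (default) the signatures are fully expressed. Systolic blood pressure
#' means are ordered A < B < C < D whenever \code{separation > 0}, and
#' template D's SBP mean exceeds 160 mmHg at every hour at the default
#' separation. Three-year mortality parameters are (0.17, 0.25, 0.16,
#' 0.20) in label order and 30-day parameters (0.03, 0.07, 0.03, 0.03),
#' the published group-level rates.
#'
#' @param hours Window length H in hours (6 default; trajectories hold
#'   their hour-6 value beyond six hours).
#' @param separation Non-negative multiplier on the signature-reference
#'   contrast.
#' @return List of four \linkS4class{PhenotypeTemplate} objects named
#'   A-D.
#' @export
makeDefaultTemplates <- function(hours = 6, separation = 1) {
  if (separation < 0) stop("separation must be non-negative")
  if (hours < 1) stop("hours must be at least 1")
  shapes <- lapply(.templateShapes(), .shapeToHours, hours = hours)
  ref <- Reduce(`+`, shapes) / length(shapes)
  noiseSd <- c(SBP = 12, DBP = 8, HR = 9, RR = 3.5, SpO2 = 1.2, Temp = 0.4)
  missingProb <- c(SBP = 0.10, DBP = 0.10, HR = 0.10, RR = 0.10,
                   SpO2 = 0.10, Temp = 0.45)
  p30 <- c(A = 0.03, B = 0.07, C = 0.03, D = 0.03)
  p3y <- c(A = 0.17, B = 0.25, C = 0.16, D = 0.20)
  out <- lapply(names(shapes), function(lab) {
    means <- ref + separation * (shapes[[lab]] - ref)
    new("PhenotypeTemplate",
        label = lab, hourlyMeans = means, noiseSd = noiseSd,
        arCoef = 0.6, missingProb = missingProb,
        p30 = unname(p30[lab]), p3y = unname(p3y[lab]))
  })
  names(out) <- names(shapes)
  if (separation > 0) {
    sbp <- vapply(out, function(t) mean(t@hourlyMeans["SBP", ]), 0)
    stopifnot(all(diff(sbp) > 0))
  }
  out
}

#' Sample survival times calibrated to a 3-year mortality probability
#'
#' Event times are exponential with rate \eqn{-\ln(1 - p_{3y}) / 1095}
#' days, so the cumulative event probability at day 1095 equals
#' \code{p3y} exactly; times beyond the follow-up horizon are
#' administratively censored.
#'
#' @param p3y 3-year mortality probability in [0, 1); 0 yields censored
#'   times only.
#' @param n Number of draws.
#' @param horizonDays Administrative censoring horizon (default 1570
#'   days, about 4.3 years of follow-up).
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{time} (days) and \code{event}
#'   (1 = death observed).
#' @export
sampleSurvival <- function(p3y, n = 1, horizonDays = 1570, seed = NULL) {
  if (horizonDays < 1) stop("horizonDays must be at least 1")
  if (p3y < 0 || p3y >= 1) stop("p3y must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (p3y == 0) {
    return(data.frame(time = rep(horizonDays, n), event = rep(0L, n)))
  }
  rate <- -log(1 - p3y) / 1095
  t <- rexp(n, rate)
  data.frame(time = pmin(t, horizonDays),
             event = as.integer(t <= horizonDays))
}

# latent AR(1) hourly paths for m encounters of one vital:
# stationary variance sd^2, lag-1 correlation ar
.latentPaths <- function(m, means, sd, ar) {
  H <- length(means)
  e <- matrix(0, m, H)
  e[, 1] <- rnorm(m, 0, sd)
  if (H > 1) {
    innovSd <- sd * sqrt(1 - ar^2)
    for (h in 2:H) e[, h] <- ar * e[, h - 1] + rnorm(m, 0, innovSd)
  }
  sweep(e, 2, means, `+`)
}

#' Generate a synthetic cohort of encounters
#'
#' Draws phenotype labels from \code{mixing}, then simulates each
#' encounter's raw vital-sign measurements, demographics, comorbidity
#' flags, organ-dysfunction score inputs and survival outcome from its
#' template. Per vital and hour, the latent value follows an AR(1)
#' process around the template trajectory; the number of raw measurements
#' in a non-missing hour is \code{max(1, Poisson(measRate))} with integer
#' minute offsets uniform within the hour; an hour is missing entirely
#' with the template's per-vital probability (temperature highest). With
#' probability \code{outlierProb} a measurement is replaced by an
#' out-of-range artifact to exercise plausibility filtering. Everything
#' is reproducible under \code{seed}.
#'
#' @param templates List of four templates from [makeDefaultTemplates()].
#' @param n Number of encounters (>= 1).
#' @param mixing Length-4 phenotype proportions summing to 1; default
#'   (0.31, 0.23, 0.31, 0.15), the published cohort composition.
#' @param seed Integer seed.
#' @param horizonDays Administrative censoring horizon in days.
#' @param measRate Poisson mean for measurements per vital per hour.
#' @param outlierProb Probability a measurement is replaced by an
#'   out-of-range artifact.
#' @return List with \code{vitals} (long table: encounter_id, vital,
#'   offset_minutes, value) and \code{encounters} (one row per encounter
#'   with true_label, demographics, comorbidities, score inputs,
#'   admission_date, time_days, event).
#' @export
generateCohort <- function(templates, n,
                           mixing = c(0.31, 0.23, 0.31, 0.15),
                           seed = 1L, horizonDays = 1570,
                           measRate = 1.5, outlierProb = 0.01) {
  if (n < 1) stop("n must be positive")
  if (length(mixing) != 4) stop("mixing must have length 4")
  if (abs(sum(mixing) - 1) > 1e-9) stop("mixing must sum to 1")
  labs <- names(templates)
  stopifnot(identical(labs, c("A", "B", "C", "D")))
  set.seed(seed)

  trueLabel <- sample(labs, n, replace = TRUE, prob = mixing)
  ids <- sprintf("E%06d", seq_len(n))
  H <- ncol(templates[[1]]@hourlyMeans)
  bounds <- plausibilityBounds()

  # per-template demographic / acuity input parameters (group-level rates
  # follow the published characteristics tables)
  ageMean <- c(A = 53, B = 50, C = 56, D = 56)
  pFemale <- c(A = 0.57, B = 0.58, C = 0.51, D = 0.53)
  pHtn <- c(A = 0.51, B = 0.51, C = 0.52, D = 0.56)
  pCvd <- c(A = 0.27, B = 0.29, C = 0.29, D = 0.32)
  pDm <- c(A = 0.23, B = 0.25, C = 0.24, D = 0.27)
  pCkd <- c(A = 0.14, B = 0.15, C = 0.16, D = 0.20)
  pVaso <- c(A = 0.32, B = 0.10, C = 0.16, D = 0.06)
  pfMean <- c(A = 380, B = 300, C = 420, D = 400)
  creaMed <- c(A = 0.9, B = 1.0, C = 0.85, D = 1.1)

  vitalsList <- vector("list", length(labs))
  encList <- vector("list", length(labs))

  for (li in seq_along(labs)) {
    lab <- labs[li]
    idx <- which(trueLabel == lab)
    m <- length(idx)
    if (m == 0) next
    tpl <- templates[[lab]]

    rows <- vector("list", length(vitalNames()))
    for (vi in seq_along(vitalNames())) {
      v <- vitalNames()[vi]
      latent <- .latentPaths(m, tpl@hourlyMeans[v, ], tpl@noiseSd[v],
                             tpl@arCoef)
      dropped <- matrix(runif(m * H) < tpl@missingProb[v], m, H)
      counts <- matrix(pmax(1L, rpois(m * H, measRate)), m, H)
      counts[dropped] <- 0L
      total <- sum(counts)
      if (total == 0) next
      encRep <- rep(rep(idx, H), as.vector(counts))
      hourRep <- rep(rep(seq_len(H), each = m), as.vector(counts))
      latRep <- rep(as.vector(latent), as.vector(counts))
      offs <- (hourRep - 1L) * 60L + as.integer(floor(runif(total) * 60))
      vals <- latRep + rnorm(total, 0, 0.25 * tpl@noiseSd[v])
      isOut <- runif(total) < outlierProb
      if (any(isOut)) {
        hi <- runif(sum(isOut)) < 0.5
        b <- bounds[[v]]
        vals[isOut] <- ifelse(hi, b[2] + runif(sum(isOut), 5, 50),
                              b[1] - runif(sum(isOut), 2, 10))
      }
      rows[[vi]] <- data.frame(
        encounter_id = ids[encRep], vital = v,
        offset_minutes = offs, value = vals,
        stringsAsFactors = FALSE
      )
    }
    vit <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])

    age <- pmin(100, pmax(18, round(rnorm(m, ageMean[lab], 18))))
    sex <- ifelse(runif(m) < pFemale[lab], "F", "M")
    gcs <- sample(c(15L, 14L, 12L, 9L, 6L, 3L), m, replace = TRUE,
                  prob = c(0.88, 0.04, 0.03, 0.02, 0.02, 0.01))
    sbpBar <- mean(tpl@hourlyMeans["SBP", ])
    dbpBar <- mean(tpl@hourlyMeans["DBP", ])
    mapBar <- dbpBar + (sbpBar - dbpBar) / 3
    surv <- sampleSurvival(tpl@p3y, n = m, horizonDays = horizonDays)
    encList[[li]] <- data.frame(
      encounter_id = ids[idx],
      true_label = lab,
      age = age,
      sex = sex,
      hypertension = as.integer(runif(m) < pHtn[lab]),
      cardiovascular = as.integer(runif(m) < pCvd[lab]),
      diabetes = as.integer(runif(m) < pDm[lab]),
      ckd = as.integer(runif(m) < pCkd[lab]),
      pao2_fio2 = pmax(60, rnorm(m, pfMean[lab], 70)),
      platelets = pmax(10, exp(rnorm(m, log(210), 0.4))),
      bilirubin = exp(rnorm(m, log(0.7), 0.6)),
      gcs = gcs,
      creatinine = exp(rnorm(m, log(creaMed[lab]), 0.4)),
      vasopressor = as.integer(runif(m) < pVaso[lab]),
      map_mmHg = rnorm(m, mapBar, 6),
      time_days = surv$time,
      event = surv$event,
      stringsAsFactors = FALSE
    )
    vitalsList[[li]] <- vit
  }

  vitals <- do.call(rbind, vitalsList[!vapply(vitalsList, is.null, TRUE)])
  vitals <- vitals[order(vitals$encounter_id, vitals$vital,
                         vitals$offset_minutes), ]
  rownames(vitals) <- NULL
  encounters <- do.call(rbind, encList[!vapply(encList, is.null, TRUE)])
  encounters <- encounters[order(encounters$encounter_id), ]
  rownames(encounters) <- NULL
  # admissions spread over a 22-month intake window, in id order, so
  # chronological splitting is exercised naturally
  encounters$admission_date <- as.Date("2014-06-01") +
    sort(sample.int(670, nrow(encounters), replace = TRUE)) - 1L

  list(vitals = vitals, encounters = encounters)
}

#' Write a generated cohort to the standard input tables
#'
#' @param cohort List from [generateCohort()].
#' @param dir Output directory (created if needed); writes
#'   \code{vitals.csv} and \code{encounters.csv}.
#' @return Invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vp <- file.path(dir, "vitals.csv")
  ep <- file.path(dir, "encounters.csv")
  writeVitals(cohort$vitals, vp)
  writeEncounters(cohort$encounters, ep)
  invisible(c(vitals = vp, encounters = ep))
}
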