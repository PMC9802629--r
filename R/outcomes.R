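# Outcome comparison across physiotypes: Kaplan-Meier estimation,
# log-rank tests, reverse-KM follow-up, covariate-adjusted Cox models
# and simple group tests with Bonferroni adjustment. Survival machinery
# delegates to the survival package (Efron tie handling); the
# module-level contracts and returned tables are defined here.

#' @importFrom survival Surv survfit survdiff coxph
#' @importFrom stats pchisq qnorm as.formula relevel
NULL

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring. S(0) = 1 and the curve
#' is non-increasing and right-continuous.
#'
#' @param time Follow-up times in days (> 0).
#' @param event Event indicator (1 = death).
#' @return Data frame with columns \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("empty survival data")
  if (any(time <= 0)) stop("times must be positive")
  fit <- survfit(Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv)
}

#' Log-rank test across groups
#'
#' Observed-minus-expected statistic over the pooled event times, with
#' \code{length(unique(group)) - 1} degrees of freedom. When no events
#' occur anywhere the statistic is 0 and p = 1 by convention, with a
#' warning.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with \code{chisq}, \code{df}, \code{p}.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("log-rank test requires at least 2 non-empty groups")
  df <- nlevels(droplevels(group)) - 1L
  if (sum(event) == 0) {
    warning("no events in any group; log-rank statistic 0 by convention")
    return(list(chisq = 0, df = df, p = 1))
  }
  sd <- survdiff(Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' The KM estimator applied with the censoring indicator inverted, so
#' censoring is the "event" and deaths are censored: the curve estimates
#' the follow-up distribution. The median is the smallest time at which
#' the curve drops strictly below 0.5 (a curve that only touches 0.5
#' keeps going); if the curve never falls below 0.5 the median is
#' open-ended and NA is returned with attribute \code{openEnded}.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = death).
#' @return Median follow-up in days, or NA with attribute
#'   \code{openEnded = TRUE}.
#' @export
reverseKmFollowup <- function(time, event) {
  if (!length(time)) stop("empty survival data")
  cens <- 1 - event
  if (sum(cens) == 0)
    return(structure(NA_real_, openEnded = TRUE))
  fit <- survfit(Surv(time, cens) ~ 1)
  below <- fit$surv < 0.5 - 1e-12
  if (!any(below)) return(structure(NA_real_, openEnded = TRUE))
  fit$time[which(below)[1]]
}

#' Covariate-adjusted Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling and Wald 95%
#' confidence intervals. The physiotype enters as indicators with C as
#' the reference level (the favorable-outcome phenotype), matching the
#' reported hazard-ratio comparisons; additional covariates (age group,
#' sex, comorbidities, acuity band) are adjusted for as supplied.
#'
#' @param data Data frame with \code{time}, \code{event}, a
#'   \code{physiotype} column and any covariate columns.
#' @param covariates Character vector of covariate column names to
#'   adjust for (may be empty).
#' @param reference Reference physiotype level (default "C").
#' @return Data frame (one row per coefficient) with \code{term},
#'   \code{hr}, \code{lower}, \code{upper}, \code{p}, plus attribute
#'   \code{reference}.
#' @export
coxFit <- function(data, covariates = character(0), reference = "C") {
  if (!all(c("time", "event", "physiotype") %in% colnames(data)))
    stop("data must carry time, event and physiotype")
  data$physiotype <- relevel(factor(data$physiotype), ref = reference)
  nev <- sum(data$event)
  npar <- nlevels(data$physiotype) - 1 + length(covariates)
  if (nev < 10 * npar)
    warning("fewer than 10 events per parameter; estimates may be unstable")
  rhs <- paste(c("physiotype", covariates), collapse = " + ")
  fit <- coxph(as.formula(paste("Surv(time, event) ~", rhs)),
               data = data, ties = "efron")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  z <- qnorm(0.975)
  out <- data.frame(
    term = names(beta),
    hr = exp(beta),
    lower = exp(beta - z * se),
    upper = exp(beta + z * se),
    p = 2 * pnorm(-abs(beta / se)),
    row.names = NULL
  )
  attr(out, "reference") <- reference
  out
}

#' Compare a variable across phenotype groups
#'
#' Chi-square test for categorical variables, one-way ANOVA for
#' normal-ish continuous variables, Kruskal-Wallis for rank-based
#' comparison — the standard bedside-table test battery.
#'
#' @param values The variable (categorical or numeric).
#' @param group Phenotype labels.
#' @param kind One of \code{"categorical"}, \code{"continuous-normal"},
#'   \code{"continuous-rank"}.
#' @return List with \code{statistic}, \code{df} (where defined) and
#'   \code{p}.
#' @export
groupCompare <- function(values, group,
                         kind = c("categorical", "continuous-normal",
                                  "continuous-rank")) {
  kind <- match.arg(kind)
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least 2 groups")
  if (kind == "categorical") {
    tab <- table(values, group)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("empty category level")
    tst <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(tst$statistic), df = unname(tst$parameter),
         p = unname(tst$p.value))
  } else if (kind == "continuous-normal") {
    av <- summary(aov(values ~ group))[[1]]
    list(statistic = av$`F value`[1], df = av$Df[1], p = av$`Pr(>F)`[1])
  } else {
    tst <- kruskal.test(values, group)
    list(statistic = unname(tst$statistic), df = unname(tst$parameter),
         p = unname(tst$p.value))
  }
}

#' Bonferroni adjustment for a fixed family size
#'
#' \code{p_adj = min(1, familySize * p)}. The family size may exceed the
#' number of p-values supplied (e.g. three per-row comparisons against
#' the reference phenotype).
#'
#' @param p Numeric p-values in [0, 1].
#' @param familySize Family size m (>= length(p)).
#' @return Adjusted p-values, never smaller than the input and never
#'   above 1.
#' @export
bonferroniAdjust <- function(p, familySize = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (familySize < length(p))
    stop("familySize must be at least the number of p-values")
  pmin(1, familySize * p)
}

#' Kaplan-Meier curves and log-rank comparison by physiotype
#'
#' @param data Data frame with \code{time}, \code{event},
#'   \code{physiotype}.
#' @return List with \code{curves} (named list of [kmEstimate()]
#'   tables) and \code{logrank}.
#' @export
survivalByPhysiotype <- function(data) {
  groups <- sort(unique(data$physiotype))
  curves <- lapply(groups, function(g) {
    sub <- data[data$physiotype == g, ]
    kmEstimate(sub$time, sub$event)
  })
  names(curves) <- groups
  list(curves = curves,
       logrank = logrankTest(data$time, data$event, data$physiotype))
}
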