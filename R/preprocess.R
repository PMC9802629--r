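# From raw irregular vital-sign series to the N x 36 clustering feature
# matrix: plausibility filtering, exclusion, hourly resampling,
# forward/backward/median imputation and z-scoring with training-cohort
# statistics.

#' Drop physiologically implausible measurements
#'
#' Removes samples outside the per-vital plausibility range; these are
#' treated as charting or device artifacts. The number of dropped rows
#' is reported via \code{message}.
#'
#' @param vitals Long-format vitals data frame (see [readVitals()]).
#' @param bounds Named list of (low, high) per vital, as from
#'   [plausibilityBounds()].
#' @return The filtered vitals data frame (possibly empty).
#' @export
filterOutliers <- function(vitals, bounds = plausibilityBounds()) {
  lo <- vapply(bounds, `[`, 0, 1)[vitals$vital]
  hi <- vapply(bounds, `[`, 0, 2)[vitals$vital]
  keep <- vitals$value >= lo & vitals$value <= hi
  nd <- sum(!keep)
  if (nd > 0) message(nd, " measurement(s) outside plausibility bounds dropped")
  out <- vitals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the missing-vitals exclusion rule
#'
#' An encounter is excluded when at least two of the six vital signs have
#' no measurement at all inside the observation window.
#'
#' @param vitals Long-format vitals data frame.
#' @param encounterIds All encounter ids under consideration (encounters
#'   with no rows at all are missing all six vitals).
#' @param windowHours Observation window in hours.
#' @return List with character vectors \code{kept} and \code{excluded}.
#' @export
excludeEncounters <- function(vitals, encounterIds, windowHours = 6) {
  inWin <- vitals[vitals$offset_minutes < windowHours * 60, , drop = FALSE]
  present <- table(factor(inWin$encounter_id, levels = encounterIds),
                   factor(inWin$vital, levels = vitalNames())) > 0
  nMissing <- length(vitalNames()) - rowSums(present)
  excluded <- encounterIds[nMissing >= 2]
  list(kept = setdiff(encounterIds, excluded), excluded = excluded)
}

#' Resample one vital-sign series to an hourly grid
#'
#' Hour bin h covers minutes [60h, 60(h+1)) (half-open); the bin value is
#' the arithmetic mean of the samples falling in the bin; empty bins are
#' masked.
#'
#' @param offsets Numeric offsets in minutes from admission.
#' @param values Measurement values, same length.
#' @param windowHours Number of hourly bins H.
#' @return List with \code{values} (length-H numeric, NA where masked)
#'   and \code{mask} (TRUE where at least one sample fell in the bin).
#' @export
resampleHourly <- function(offsets, values, windowHours = 6) {
  H <- as.integer(windowHours)
  keep <- offsets >= 0 & offsets < H * 60
  bin <- floor(offsets[keep] / 60) + 1L
  sums <- tabulate(bin, nbins = H)
  vals <- rep(NA_real_, H)
  if (any(keep)) {
    agg <- vapply(split(values[keep], bin), mean, 0)
    vals[as.integer(names(agg))] <- agg
  }
  list(values = vals, mask = sums > 0)
}

#' Build per-encounter hourly vital grids
#'
#' @param vitals Long-format vitals data frame (already
#'   plausibility-filtered).
#' @param encounterIds Encounters to build grids for.
#' @param windowHours Window length H.
#' @return Named list of \linkS4class{VitalGrid} objects.
#' @export
buildGrids <- function(vitals, encounterIds, windowHours = 6) {
  H <- as.integer(windowHours)
  byEnc <- split(vitals, factor(vitals$encounter_id, levels = encounterIds))
  out <- lapply(encounterIds, function(id) {
    df <- byEnc[[id]]
    vals <- matrix(NA_real_, 6, H,
                   dimnames = list(vitalNames(), paste0("h", seq_len(H))))
    mask <- matrix(FALSE, 6, H, dimnames = dimnames(vals))
    if (!is.null(df) && nrow(df)) {
      for (v in intersect(vitalNames(), unique(df$vital))) {
        sub <- df[df$vital == v, ]
        rs <- resampleHourly(sub$offset_minutes, sub$value, H)
        vals[v, ] <- rs$values
        mask[v, ] <- rs$mask
      }
    }
    src <- matrix("", 6, H, dimnames = dimnames(vals))
    src[mask] <- "observed"
    new("VitalGrid", encounterId = id, values = vals,
        observedMask = mask, source = src)
  })
  names(out) <- encounterIds
  out
}

#' Per-(vital, hour) training medians
#'
#' Median of the observed hourly values across a set of (training) grids,
#' used as the fallback for encounters with no measurements of a vital in
#' the window. A cell with no observation anywhere falls back to the
#' vital's overall median; a vital never observed in the whole training
#' set is an error.
#'
#' @param grids List of \linkS4class{VitalGrid}.
#' @return 6 x H numeric matrix of medians.
#' @export
trainingMedians <- function(grids) {
  H <- ncol(grids[[1]]@values)
  med <- matrix(NA_real_, 6, H,
                dimnames = list(vitalNames(), paste0("h", seq_len(H))))
  allVals <- lapply(grids, function(g) {
    v <- g@values
    v[!g@observedMask] <- NA
    v
  })
  arr <- simplify2array(allVals)  # 6 x H x N
  for (v in seq_len(6)) {
    rowAll <- as.vector(arr[v, , ])
    if (all(is.na(rowAll)))
      stop("vital ", vitalNames()[v], " never observed in training set")
    for (h in seq_len(H)) {
      x <- arr[v, h, ]
      med[v, h] <- if (all(is.na(x))) median(rowAll, na.rm = TRUE)
                   else median(x, na.rm = TRUE)
    }
  }
  med
}

# forward then backward fill of one numeric vector with provenance tags
.fillRow <- function(x) {
  H <- length(x)
  src <- ifelse(is.na(x), "", "observed")
  last <- NA_real_
  for (h in seq_len(H)) {      # forward pass
    if (is.na(x[h])) {
      if (!is.na(last)) { x[h] <- last; src[h] <- "forward" }
    } else last <- x[h]
  }
  nxt <- NA_real_
  for (h in rev(seq_len(H))) { # backward pass for leading gaps
    if (is.na(x[h])) {
      if (!is.na(nxt)) { x[h] <- nxt; src[h] <- "backward" }
    } else if (src[h] == "observed") nxt <- x[h]
  }
  list(values = x, source = src)
}

#' Impute a vital grid
#'
#' Per vital row: forward fill from the most recent observed hour, then
#' backward fill any leading gap; rows with no observation at all take
#' the per-(vital, hour) training medians. Every imputed cell is tagged
#' with its provenance; the observation mask is never altered.
#'
#' @param grid A \linkS4class{VitalGrid}.
#' @param medians 6 x H training median matrix from [trainingMedians()].
#' @return The imputed \linkS4class{VitalGrid} (all values finite).
#' @export
imputeGrid <- function(grid, medians) {
  if (!identical(dim(medians), dim(grid@values)) || any(!is.finite(medians)))
    stop("training medians must be a complete matrix matching the grid")
  vals <- grid@values
  src <- grid@source
  for (v in seq_len(nrow(vals))) {
    if (!any(grid@observedMask[v, ])) {
      vals[v, ] <- medians[v, ]
      src[v, ] <- "median"
    } else {
      f <- .fillRow(ifelse(grid@observedMask[v, ], vals[v, ], NA_real_))
      vals[v, ] <- f$values
      src[v, ] <- f$source
    }
  }
  new("VitalGrid", encounterId = grid@encounterId, values = vals,
      observedMask = grid@observedMask, source = src)
}

#' Build the standardized feature matrix
#'
#' Flattens imputed grids into (vital, hour) features, ordered
#' vital-major and hour-minor (6 vitals x 6 hours = 36 features by
#' default), and z-scores each feature. In fitting mode the per-feature
#' mean and SD are estimated from the supplied (training) grids and
#' stored; otherwise the supplied standardization is applied unchanged,
#' which is how validation and test cohorts are projected into the
#' training feature space.
#'
#' @param grids List of imputed \linkS4class{VitalGrid}.
#' @param includedVitals Vitals to keep as features.
#' @param fitStandardization If TRUE, fit mean/SD on these grids.
#' @param standardize Data frame (feature, mean, sd) required when
#'   \code{fitStandardization = FALSE}.
#' @param colData Optional per-encounter data frame (row order matching
#'   \code{grids}) stored alongside the features.
#' @return A \linkS4class{PhysioFeatureSet}.
#' @export
buildFeatures <- function(grids, includedVitals = vitalNames(),
                          fitStandardization = TRUE, standardize = NULL,
                          colData = NULL) {
  H <- ncol(grids[[1]]@values)
  featNames <- as.vector(t(outer(includedVitals, seq_len(H), paste, sep = ".h")))
  X <- t(vapply(grids, function(g) {
    if (any(!is.finite(g@values[includedVitals, ])))
      stop("grids must be imputed before feature construction")
    as.vector(t(g@values[includedVitals, , drop = FALSE]))
  }, numeric(length(featNames))))
  colnames(X) <- featNames
  rownames(X) <- vapply(grids, function(g) g@encounterId, "")

  if (fitStandardization) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    if (any(sdv == 0))
      stop("zero-variance feature in fitting mode: ",
           paste(featNames[sdv == 0], collapse = ", "))
    standardize <- data.frame(feature = featNames, mean = mu, sd = sdv,
                              row.names = NULL)
  } else {
    if (is.null(standardize))
      stop("standardize must be supplied when fitStandardization = FALSE")
    if (!identical(standardize$feature, featNames))
      stop("standardization features do not match the grid features")
  }
  Z <- sweep(sweep(X, 2, standardize$mean), 2, standardize$sd, `/`)

  rd <- S4Vectors::DataFrame(
    vital = rep(includedVitals, each = H),
    hour = rep(seq_len(H), times = length(includedVitals)),
    row.names = featNames
  )
  cd <- if (is.null(colData)) {
    S4Vectors::DataFrame(row.names = rownames(X))
  } else {
    S4Vectors::DataFrame(colData, row.names = rownames(X))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(Z)),
    rowData = rd, colData = cd,
    metadata = list(standardization = standardize, windowHours = H)
  )
  new("PhysioFeatureSet", se)
}

#' Invert the standardization of a feature matrix
#'
#' @param Z Standardized N x F matrix.
#' @param standardize Data frame (feature, mean, sd).
#' @return Raw-scale N x F matrix.
#' @export
destandardize <- function(Z, standardize) {
  sweep(sweep(Z, 2, standardize$sd, `*`), 2, standardize$mean, `+`)
}

#' Full preprocessing pipeline for one cohort
#'
#' Plausibility filtering, exclusion, hourly resampling, imputation and
#' feature construction in one call. In training mode (no
#' \code{standardize}/\code{medians} supplied) the training medians and
#' standardization are fitted on this cohort and returned for reuse on
#' later cohorts.
#'
#' @param vitals Long-format vitals table.
#' @param encounters Per-encounter table (optional; carried into
#'   \code{colData}).
#' @param config A [runConfig()].
#' @param standardize Optional training standardization to apply.
#' @param medians Optional training median matrix to apply.
#' @return List with \code{features} (a
#'   \linkS4class{PhysioFeatureSet}), \code{grids}, \code{kept},
#'   \code{excluded}, \code{medians} and \code{standardization}.
#' @export
preprocessCohort <- function(vitals, encounters = NULL,
                             config = runConfig(), standardize = NULL,
                             medians = NULL) {
  vitals <- validateVitals(vitals)
  ids <- if (is.null(encounters)) unique(vitals$encounter_id)
         else encounters$encounter_id
  clean <- filterOutliers(vitals, config$bounds)
  excl <- excludeEncounters(clean, ids, config$windowHours)
  if (!length(excl$kept)) stop("no encounters left after exclusion")
  grids <- buildGrids(clean[clean$encounter_id %in% excl$kept, ],
                      excl$kept, config$windowHours)
  if (is.null(medians)) medians <- trainingMedians(grids)
  grids <- lapply(grids, imputeGrid, medians = medians)
  cd <- if (is.null(encounters)) NULL
        else encounters[match(excl$kept, encounters$encounter_id), , drop = FALSE]
  fs <- buildFeatures(grids, config$includedVitals,
                      fitStandardization = is.null(standardize),
                      standardize = standardize, colData = cd)
  list(features = fs, grids = grids, kept = excl$kept,
       excluded = excl$excluded, medians = medians,
       standardization = standardization(fs))
}
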