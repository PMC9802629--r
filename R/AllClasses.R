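#' @import methods
#' @importFrom stats median sd var rnorm runif rexp rpois prcomp kmeans
#'   dist aov kruskal.test chisq.test setNames pchisq pnorm qnorm coef
#'   as.formula relevel
#' @importFrom utils read.csv write.csv tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Canonical vital-sign names
#'
#' The six bedside vital signs the pipeline operates on, in canonical order:
#' systolic and diastolic blood pressure (mmHg), heart rate (bpm),
#' respiratory rate (breaths/min), peripheral oxygen saturation (%) and
#' temperature (degrees C).
#'
#' @return Character vector of length six.
#' @export
vitalNames <- function() c("SBP", "DBP", "HR", "RR", "SpO2", "Temp")

#' PhenotypeTemplate: the generative description of one physiotype
#'
#' Holds the per-vital hourly mean trajectories, noise model, missingness
#' and mortality parameters used by the synthetic cohort generator. The
#' four default templates emulate the four published physiologic
#' signatures: persistent hypotension without compensatory tachycardia
#' (A), tachycardia/tachypnea/hypoxemia (B), minimal derangement (C) and
#' severe hypertension (D), labeled by ascending systolic blood pressure.
#'
#' @slot label Single letter, one of "A", "B", "C", "D".
#' @slot hourlyMeans 6 x H numeric matrix (vital x hour) of mean
#'   trajectories; rows named by [vitalNames()].
#' @slot noiseSd Per-vital within-encounter SD (length 6, named).
#' @slot arCoef Lag-1 autocorrelation of the latent hourly process, in
#'   [0, 1).
#' @slot missingProb Per-vital probability that a given hour has no raw
#'   measurement (length 6, named, in [0, 1]).
#' @slot p30 30-day mortality probability.
#' @slot p3y 3-year mortality probability (calibrates the exponential
#'   hazard used for event-time sampling).
#'
#' @export
setClass("PhenotypeTemplate",
  representation(
    label = "character",
    hourlyMeans = "matrix",
    noiseSd = "numeric",
    arCoef = "numeric",
    missingProb = "numeric",
    p30 = "numeric",
    p3y = "numeric"
  )
)

setValidity("PhenotypeTemplate", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@hourlyMeans), vitalNames()))
    msg <- c(msg, "hourlyMeans rows must be the six canonical vitals")
  if (any(!is.finite(object@hourlyMeans)))
    msg <- c(msg, "hourlyMeans must be finite")
  if (any(object@missingProb < 0 | object@missingProb > 1))
    msg <- c(msg, "missingProb must lie in [0, 1]")
  if (object@arCoef < 0 || object@arCoef >= 1)
    msg <- c(msg, "arCoef must lie in [0, 1)")
  if (object@p3y < 0 || object@p3y > 1)
    msg <- c(msg, "p3y must lie in [0, 1]")
  # coarse physiologic plausibility for the mean trajectories
  lims <- plausibilityBounds()
  for (v in vitalNames()) {
    if (any(object@hourlyMeans[v, ] < lims[[v]][1] |
            object@hourlyMeans[v, ] > lims[[v]][2]))
      msg <- c(msg, sprintf("hourly means for %s outside physiologic bounds", v))
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PhenotypeTemplate", function(object) {
  cat(sprintf(
    "PhenotypeTemplate %s: %d h, mean SBP %.1f mmHg, p3y %.2f\n",
    object@label, ncol(object@hourlyMeans),
    mean(object@hourlyMeans["SBP", ]), object@p3y
  ))
})

#' VitalGrid: one encounter's hourly vital-sign matrix
#'
#' The 6 x H per-encounter matrix produced by hourly resampling, together
#' with the observation mask and, after imputation, the provenance of each
#' cell value.
#'
#' @slot encounterId Encounter identifier.
#' @slot values 6 x H numeric matrix (vital x hour); NA where the hour is
#'   unobserved and not yet imputed.
#' @slot observedMask 6 x H logical matrix; TRUE where at least one raw
#'   measurement fell in that hour.
#' @slot source 6 x H character matrix with per-cell provenance tags:
#'   "observed", "forward", "backward" or "median" ("" before imputation).
#'
#' @export
setClass("VitalGrid",
  representation(
    encounterId = "character",
    values = "matrix",
    observedMask = "matrix",
    source = "matrix"
  )
)

setValidity("VitalGrid", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (!identical(d, dim(object@observedMask)) ||
      !identical(d, dim(object@source)))
    msg <- c(msg, "values, observedMask and source must share dimensions")
  if (!identical(rownames(object@values), vitalNames()))
    msg <- c(msg, "rows must be the six canonical vitals")
  obs <- object@observedMask & object@source != ""
  if (any(object@source[obs] != "observed"))
    msg <- c(msg, "observed cells must carry tag 'observed'")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "VitalGrid", function(object) {
  cat(sprintf(
    "VitalGrid %s: %d vitals x %d hours, %d/%d hours observed\n",
    object@encounterId, nrow(object@values), ncol(object@values),
    sum(object@observedMask), length(object@observedMask)
  ))
})

#' PhysioFeatureSet: the standardized clustering feature matrix
#'
#' A \linkS4class{SummarizedExperiment} holding the F x N matrix of
#' z-scored (vital, hour) features (assay \code{"features"}), feature
#' annotation in \code{rowData} (vital, hour) and per-encounter metadata
#' in \code{colData}. The standardization parameters fitted on the
#' training cohort live in \code{metadata(x)$standardization} so they can
#' be re-applied, never refitted, to validation and test cohorts.
#'
#' @export
setClass("PhysioFeatureSet", contains = "SummarizedExperiment")

setValidity("PhysioFeatureSet", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' required")
  st <- S4Vectors::metadata(object)$standardization
  if (is.null(st) || !all(c("mean", "sd") %in% colnames(st)))
    msg <- c(msg, "metadata standardization with columns mean, sd required")
  else if (any(st$sd <= 0))
    msg <- c(msg, "standardization sd must be > 0 for every feature")
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: consensus clustering over a range of k
#'
#' Per-k consensus matrices and their CDF areas, the delta-area model
#' selection trace, the selected number of clusters, the final full-data
#' partition and the within-cluster consensus diagnostics.
#'
#' @slot kRange Integer vector of candidate cluster numbers (contiguous
#'   from 2).
#' @slot consensusMatrices Named list of N x N consensus matrices, one
#'   per k.
#' @slot areas Named numeric: area under the consensus CDF per k.
#' @slot deltaAreas Named numeric: relative change in area per k.
#' @slot selectedK Selected number of clusters.
#' @slot finalLabels Integer partition of the N items at selectedK.
#' @slot clusterConsensus Named numeric: mean within-cluster pairwise
#'   consensus for each final cluster.
#'
#' @export
setClass("ConsensusResult",
  representation(
    kRange = "integer",
    consensusMatrices = "list",
    areas = "numeric",
    deltaAreas = "numeric",
    selectedK = "integer",
    finalLabels = "integer",
    clusterConsensus = "numeric"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character(0)
  for (M in object@consensusMatrices) {
    if (max(abs(M - t(M))) > 1e-12)
      msg <- c(msg, "consensus matrices must be symmetric")
    if (min(M) < -1e-12 || max(M) > 1 + 1e-12)
      msg <- c(msg, "consensus entries must lie in [0, 1]")
  }
  if (length(object@finalLabels) &&
      length(unique(object@finalLabels)) != object@selectedK)
    msg <- c(msg, "finalLabels must take exactly selectedK distinct values")
  if (length(msg)) unique(msg) else TRUE
})

#' @export
setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: k in %d..%d, selected k = %d (N = %d)\n",
    min(object@kRange), max(object@kRange), object@selectedK,
    length(object@finalLabels)
  ))
  cat("  CDF areas:  ",
      paste(sprintf("k=%d %.3f", object@kRange, object@areas), collapse = "  "),
      "\n")
  cat("  delta area: ",
      paste(sprintf("k=%d %.3f", object@kRange, object@deltaAreas),
            collapse = "  "), "\n")
})

#' PhysiotypeModel: the portable centroid prediction artifact
#'
#' Labeled cluster centroids in standardized feature space plus the
#' training standardization parameters. This is everything needed to
#' assign physiotypes to new encounters by minimum Euclidean distance,
#' without access to the training data.
#'
#' @slot centroids k x F numeric matrix in standardized feature space,
#'   rows named with the physiotype letters.
#' @slot labelOrder Named integer: original cluster index for each letter.
#' @slot standardization Data frame with columns feature, mean, sd copied
#'   from the training feature set.
#' @slot featureNames Ordered feature names (vital-major, hour-minor).
#'
#' @export
setClass("PhysiotypeModel",
  representation(
    centroids = "matrix",
    labelOrder = "integer",
    standardization = "data.frame",
    featureNames = "character"
  )
)

setValidity("PhysiotypeModel", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (!identical(colnames(object@centroids), object@featureNames))
    msg <- c(msg, "centroid columns must match featureNames")
  if (nrow(object@standardization) != length(object@featureNames))
    msg <- c(msg, "standardization must cover every feature")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PhysiotypeModel", function(object) {
  cat(sprintf(
    "PhysiotypeModel: %d centroids (%s) over %d features\n",
    nrow(object@centroids), paste(rownames(object@centroids), collapse = ","),
    length(object@featureNames)
  ))
})

#' GmmFit: a diagonal-covariance Gaussian mixture fit
#'
#' @slot nComponents Number of mixture components.
#' @slot weights Mixing weights (sum to 1).
#' @slot means k x F component means.
#' @slot variances k x F diagonal component variances.
#' @slot responsibilities N x k posterior membership probabilities.
#' @slot logLik Final log-likelihood.
#' @slot logLikTrace Per-iteration log-likelihood of the best EM run
#'   (non-decreasing).
#' @slot bic Bayesian information criterion, -2 logL + p log N.
#'
#' @export
setClass("GmmFit",
  representation(
    nComponents = "integer",
    weights = "numeric",
    means = "matrix",
    variances = "matrix",
    responsibilities = "matrix",
    logLik = "numeric",
    logLikTrace = "numeric",
    bic = "numeric"
  )
)

setValidity("GmmFit", function(object) {
  msg <- character(0)
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  rs <- rowSums(object@responsibilities)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "responsibility rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GmmFit", function(object) {
  cat(sprintf(
    "GmmFit: %d components, logL = %.2f, BIC = %.2f\n",
    object@nComponents, object@logLik, object@bic
  ))
})

#' SomMosaic: a trained self-organizing map over the feature space
#'
#' @slot codebook (G*G) x F matrix of node codebook vectors.
#' @slot gridSize G, the side length of the square node grid.
#' @slot gridCoords (G*G) x 2 integer node coordinates.
#' @slot bmu Integer best-matching node per training encounter.
#' @slot quantizationError Mean distance to the BMU per epoch.
#'
#' @export
setClass("SomMosaic",
  representation(
    codebook = "matrix",
    gridSize = "integer",
    gridCoords = "matrix",
    bmu = "integer",
    quantizationError = "numeric"
  )
)

#' @export
setMethod("show", "SomMosaic", function(object) {
  cat(sprintf(
    "SomMosaic: %d x %d grid, %d features, final QE %.4f\n",
    object@gridSize, object@gridSize, ncol(object@codebook),
    tail(object@quantizationError, 1)
  ))
})
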