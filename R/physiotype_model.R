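# The portable prediction artifact: labeled centroids plus training
# standardization, and nearest-centroid prediction for new encounters.

#' Derive a labeled physiotype model from a partition
#'
#' Each cluster's centroid is the mean of its members' standardized
#' feature vectors. Clusters are then assigned letters by ascending mean
#' raw (de-standardized) systolic blood pressure across the window's
#' hourly SBP features: the lowest-SBP cluster becomes "A" and the
#' highest "D" (letters continue alphabetically if the partition has a
#' different number of clusters).
#'
#' @param features A \linkS4class{PhysioFeatureSet} (training cohort).
#' @param labels Cluster labels, one per encounter.
#' @return A \linkS4class{PhysiotypeModel}.
#' @export
deriveModel <- function(features, labels) {
  X <- featureMatrix(features)
  st <- standardization(features)
  if (length(labels) != nrow(X))
    stop("labels must match the number of encounters")
  clusters <- sort(unique(labels))
  if (any(table(labels) == 0) || length(clusters) < 2)
    stop("need at least two non-empty clusters")
  cent <- t(vapply(clusters, function(c)
    colMeans(X[labels == c, , drop = FALSE]), numeric(ncol(X))))
  colnames(cent) <- colnames(X)

  sbpCols <- grep("^SBP\\.", colnames(X))
  if (!length(sbpCols))
    stop("model labeling requires SBP features")
  rawCent <- destandardize(cent, st)
  sbpMean <- rowMeans(rawCent[, sbpCols, drop = FALSE])
  ord <- order(sbpMean)
  letters <- LETTERS[seq_along(clusters)]
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- letters
  labelOrder <- setNames(as.integer(clusters[ord]), letters)

  new("PhysiotypeModel",
      centroids = cent, labelOrder = labelOrder,
      standardization = st, featureNames = colnames(X))
}

#' Predict physiotypes by minimum Euclidean distance to centroids
#'
#' New encounters' raw (vital, hour) features are standardized with the
#' model's stored training means and SDs (never refitted) and assigned
#' to the physiotype with the nearest centroid. Distance ties break
#' toward the earlier letter.
#'
#' @param model A \linkS4class{PhysiotypeModel}.
#' @param newdata Raw-scale N x F feature matrix with columns matching
#'   the model's features, or a \linkS4class{PhysioFeatureSet} already
#'   standardized with the model's parameters.
#' @return Data frame with \code{label} and one distance column per
#'   physiotype.
#' @export
predictPhysiotype <- function(model, newdata) {
  if (is(newdata, "PhysioFeatureSet")) {
    if (!isTRUE(all.equal(standardization(newdata)$mean,
                          model@standardization$mean)) ||
        !isTRUE(all.equal(standardization(newdata)$sd,
                          model@standardization$sd)))
      stop("feature set was standardized with different parameters than the model")
    Z <- featureMatrix(newdata)
  } else {
    X <- as.matrix(newdata)
    if (is.null(colnames(X)) || !identical(colnames(X), model@featureNames))
      stop("feature names do not match the model")
    Z <- sweep(sweep(X, 2, model@standardization$mean), 2,
               model@standardization$sd, `/`)
  }
  cent <- model@centroids
  d2 <- vapply(seq_len(nrow(cent)), function(j)
    rowSums(sweep(Z, 2, cent[j, ])^2), numeric(nrow(Z)))
  if (nrow(Z) == 1) d2 <- matrix(d2, nrow = 1)
  dist <- sqrt(d2)
  colnames(dist) <- rownames(cent)
  # ties (within float tolerance) break toward the earlier letter
  lab <- rownames(cent)[apply(dist, 1, function(d)
    which(d <= min(d) + 1e-9 * (1 + min(d)))[1])]
  out <- data.frame(label = lab, dist, row.names = rownames(Z),
                    check.names = FALSE)
  out
}

#' @describeIn predictPhysiotype Method form, \code{predict(model, newdata)}.
#' @param object A \linkS4class{PhysiotypeModel}.
#' @export
setMethod("predict", "PhysiotypeModel", function(object, newdata) {
  predictPhysiotype(object, newdata)
})

#' Serialize a physiotype model to a flat text file
#'
#' The model is written as JSON at full double precision, so a
#' round-trip through [readPhysiotypeModel()] reproduces predictions
#' bit-exactly. The artifact is self-contained: validation and test
#' stages need no training data.
#'
#' @param model A \linkS4class{PhysiotypeModel}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writePhysiotypeModel <- function(model, path) {
  obj <- list(
    featureNames = model@featureNames,
    labels = rownames(model@centroids),
    labelOrder = as.list(model@labelOrder),
    centroids = apply(model@centroids, 1, identity, simplify = FALSE),
    standardization = list(mean = model@standardization$mean,
                           sd = model@standardization$sd)
  )
  # 17 significant digits reproduce IEEE doubles exactly on re-parse
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a serialized physiotype model
#'
#' @param path Path written by [writePhysiotypeModel()].
#' @return A \linkS4class{PhysiotypeModel}.
#' @export
readPhysiotypeModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  featureNames <- obj$featureNames
  cent <- do.call(rbind, obj$centroids[obj$labels])
  colnames(cent) <- featureNames
  rownames(cent) <- obj$labels
  st <- data.frame(feature = featureNames,
                   mean = obj$standardization$mean,
                   sd = obj$standardization$sd, row.names = NULL)
  new("PhysiotypeModel",
      centroids = cent,
      labelOrder = setNames(as.integer(unlist(obj$labelOrder)),
                            names(obj$labelOrder)),
      standardization = st, featureNames = featureNames)
}
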