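# Phenotype characterization: pairwise standardized mean differences,
# self-organizing-map vital mosaics and a 2-D embedding for
# visualization. All operations are read-only on labels and features.

#' Pairwise standardized mean differences between two phenotypes
#'
#' Restricts the feature matrix to the members of two phenotypes,
#' re-standardizes every feature on the pooled pair (mean 0, SD 1), and
#' reports each group's mean per feature. A group mean of +1 means the
#' group sits one pooled SD above the pair as a whole. Features are
#' ranked by the absolute between-group difference, which identifies the
#' vitals that drive the separation of that pair.
#'
#' @param features \linkS4class{PhysioFeatureSet} or N x F matrix.
#' @param labels Phenotype labels, one per encounter.
#' @param pair Length-2 vector of labels to compare.
#' @return Data frame with columns \code{feature}, \code{mean_1},
#'   \code{mean_2} (in \code{pair} order), \code{difference} and
#'   \code{rank}, ordered by decreasing \code{abs(difference)}.
#' @export
smdPairwise <- function(features, labels, pair) {
  if (is(features, "PhysioFeatureSet")) features <- featureMatrix(features)
  X <- as.matrix(features)
  if (!all(pair %in% labels)) stop("both pair labels must be present")
  idx1 <- which(labels == pair[1])
  idx2 <- which(labels == pair[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("each group needs at least 2 members")
  sub <- X[c(idx1, idx2), , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, sd)
  sdv[sdv == 0] <- 1  # a constant feature separates nothing
  Z <- sweep(sweep(sub, 2, mu), 2, sdv, `/`)
  g <- rep(c(1, 2), c(length(idx1), length(idx2)))
  m1 <- colMeans(Z[g == 1, , drop = FALSE])
  m2 <- colMeans(Z[g == 2, , drop = FALSE])
  out <- data.frame(feature = colnames(X), mean_1 = m1, mean_2 = m2,
                    difference = m1 - m2, row.names = NULL)
  out <- out[order(-abs(out$difference)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Train a self-organizing map on the feature space
#'
#' Online Kohonen updates on a square G x G node grid: each presented
#' encounter pulls its best-matching node and the node's grid
#' neighborhood toward it, with a learning rate decaying linearly from
#' \code{lrStart} to \code{lrEnd} and a Gaussian neighborhood whose
#' radius decays from G/2 to 0.5 over the run. The mean distance to the
#' best-matching node (quantization error) is recorded per epoch.
#' Deterministic under \code{seed}.
#'
#' @param features \linkS4class{PhysioFeatureSet} or N x F matrix.
#' @param gridSize G >= 2, side of the square node grid (default 8).
#' @param epochs Training epochs (default 20).
#' @param seed Integer seed.
#' @param lrStart,lrEnd Learning-rate schedule endpoints.
#' @return A \linkS4class{SomMosaic}.
#' @export
trainSom <- function(features, gridSize = 8L, epochs = 20L, seed = 1L,
                     lrStart = 0.5, lrEnd = 0.01) {
  if (is(features, "PhysioFeatureSet")) features <- featureMatrix(features)
  X <- as.matrix(features)
  if (!nrow(X)) stop("empty features")
  if (gridSize < 2) stop("gridSize must be at least 2")
  set.seed(seed)
  G <- as.integer(gridSize)
  nNodes <- G * G
  coords <- as.matrix(expand.grid(gx = seq_len(G), gy = seq_len(G)))
  gridD2 <- as.matrix(dist(coords))^2
  codebook <- X[sample.int(nrow(X), nNodes, replace = nrow(X) < nNodes), ,
                drop = FALSE]
  totalSteps <- epochs * nrow(X)
  sigStart <- G / 2
  sigEnd <- 0.5
  step <- 0
  qe <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(X))
    dists <- numeric(nrow(X))
    for (ii in seq_along(ord)) {
      x <- X[ord[ii], ]
      frac <- step / max(1, totalSteps - 1)
      lr <- lrStart + frac * (lrEnd - lrStart)
      sig <- sigStart + frac * (sigEnd - sigStart)
      d2 <- rowSums(sweep(codebook, 2, x)^2)
      bmu <- which.min(d2)
      dists[ii] <- sqrt(d2[bmu])
      # Gaussian weights within the shrinking radius; once the radius
      # reaches its floor only the winning node is updated
      h <- exp(-gridD2[, bmu] / (2 * sig^2))
      active <- gridD2[, bmu] <= sig^2 + 1e-12
      codebook[active, ] <- codebook[active, , drop = FALSE] +
        lr * h[active] * sweep(-codebook[active, , drop = FALSE], 2, x, `+`)
      step <- step + 1
    }
    qe[ep] <- mean(dists)
  }
  bmu <- apply(X, 1, function(x)
    which.min(rowSums(sweep(codebook, 2, x)^2)))
  new("SomMosaic", codebook = codebook, gridSize = G,
      gridCoords = coords, bmu = as.integer(bmu),
      quantizationError = qe)
}

#' Average vital-sign mosaic for one phenotype
#'
#' The phenotype's members are mapped to their best-matching nodes; the
#' mosaic is the occupancy-weighted average of the occupied codebook
#' vectors, and the occupancy map counts members per node (summing to
#' the phenotype's size).
#'
#' @param som A trained \linkS4class{SomMosaic}.
#' @param labels Phenotype labels matching the SOM's training
#'   encounters.
#' @param phenotype The phenotype to summarize.
#' @return List with \code{mosaic} (F-vector: occupancy-weighted mean
#'   codebook), \code{occupancy} (G x G matrix), \code{modalNode}.
#' @export
mosaicForPhenotype <- function(som, labels, phenotype) {
  if (length(labels) != length(som@bmu))
    stop("labels must match the SOM's training encounters")
  idx <- which(labels == phenotype)
  if (!length(idx)) stop("phenotype absent from labels")
  nodes <- som@bmu[idx]
  occ <- tabulate(nodes, nbins = som@gridSize^2)
  mosaic <- colSums(som@codebook * occ) / sum(occ)
  list(
    mosaic = mosaic,
    occupancy = matrix(occ, som@gridSize, som@gridSize),
    modalNode = which.max(occ)
  )
}

#' 2-D embedding of the feature space for visualization
#'
#' Projects encounters onto the first two principal components. The
#' contract is visual: on separable cohorts, the mean within-phenotype
#' pairwise distance is smaller than the between-phenotype distance.
#' Deterministic (the PC sign convention is fixed by the largest
#' loading).
#'
#' @param features \linkS4class{PhysioFeatureSet} or N x F matrix.
#' @param seed Unused by the deterministic projection; kept so
#'   stochastic embeddings can be swapped in without an interface
#'   change.
#' @return N x 2 coordinate matrix.
#' @export
embed2d <- function(features, seed = 1L) {
  if (is(features, "PhysioFeatureSet")) features <- featureMatrix(features)
  X <- as.matrix(features)
  if (nrow(X) < 5) stop("embedding requires at least 5 encounters")
  if (all(apply(X, 2, sd) == 0)) stop("features are constant")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  Y <- pc$x[, 1:2, drop = FALSE]
  # fix signs so runs are comparable
  for (j in 1:2) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) Y[, j] <- -Y[, j]
  }
  colnames(Y) <- c("dim1", "dim2")
  Y
}
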