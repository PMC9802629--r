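# Consensus k-means clustering with subsample resampling, consensus-CDF
# model selection (delta-area rule) and within-cluster consensus
# diagnostics.

#' Resampling scheme for consensus clustering
#'
#' @param nResamples Number of resamples (>= 2); 100 by default, the
#'   method's conventional setting.
#' @param subsampleFraction Fraction of items drawn without replacement
#'   in each resample, in (0, 1]; 0.8 by default.
#' @param baseSeed Base of the seed ladder: resample r runs under seed
#'   \code{baseSeed + r}, so any single resample can be replayed.
#' @return List with class \code{"resampleScheme"}.
#' @export
resampleScheme <- function(nResamples = 100L, subsampleFraction = 0.8,
                           baseSeed = 1L) {
  if (nResamples < 2) stop("nResamples must be at least 2")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("subsampleFraction must lie in (0, 1]")
  structure(list(nResamples = as.integer(nResamples),
                 subsampleFraction = subsampleFraction,
                 baseSeed = as.integer(baseSeed)),
            class = "resampleScheme")
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding)
.kmppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Seeded k-means partition
#'
#' Lloyd's algorithm with k-means++ seeding, best of \code{restarts}
#' restarts by total within-cluster sum of squares; deterministic under
#' \code{seed}.
#'
#' @param X N x F numeric matrix.
#' @param k Number of clusters (<= N).
#' @param seed Integer seed.
#' @param restarts Number of restarts.
#' @return Integer labels of length N with attribute \code{"wcss"}.
#' @export
kmeansPartition <- function(X, k, seed = 1L, restarts = 5L) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty input")
  if (k > nrow(X)) stop("k must not exceed the number of items")
  if (any(!is.finite(X))) stop("X must be finite")
  set.seed(seed)
  if (k == 1) {
    wcss <- sum(sweep(X, 2, colMeans(X))^2)
    return(structure(rep(1L, nrow(X)), wcss = wcss))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmppCenters(X, k)
    km <- suppressWarnings(
      kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(as.integer(best$cluster), wcss = best$tot.withinss)
}

#' Consensus matrix for one value of k
#'
#' For each resample, draws \code{ceiling(fraction * N)} items without
#' replacement and clusters them with [kmeansPartition()]. Entry (i, j)
#' of the consensus matrix is the number of resamples in which i and j
#' were co-clustered divided by the number in which both were sampled;
#' pairs never co-sampled get 0 with a warning. The diagonal is 1.
#'
#' @param X N x F numeric matrix.
#' @param k Number of clusters.
#' @param scheme A [resampleScheme()].
#' @return N x N symmetric matrix with attribute \code{"cosampled"}, the
#'   pair co-sampling counts.
#' @export
consensusMatrix <- function(X, k, scheme = resampleScheme()) {
  X <- as.matrix(X)
  n <- nrow(X)
  together <- matrix(0, n, n)
  cosampled <- matrix(0, n, n)
  nSub <- ceiling(scheme$subsampleFraction * n)
  for (r in seq_len(scheme$nResamples)) {
    seedR <- scheme$baseSeed + r
    set.seed(seedR)
    idx <- sample.int(n, nSub)
    labs <- kmeansPartition(X[idx, , drop = FALSE], k, seed = seedR)
    conn <- outer(labs, labs, `==`) * 1
    together[idx, idx] <- together[idx, idx] + conn
    cosampled[idx, idx] <- cosampled[idx, idx] + 1
  }
  M <- matrix(0, n, n)
  seen <- cosampled > 0
  M[seen] <- together[seen] / cosampled[seen]
  if (any(!seen[upper.tri(seen)]))
    warning("some pairs were never co-sampled; their consensus is 0")
  diag(M) <- 1
  dimnames(M) <- list(rownames(X), rownames(X))
  structure(M, cosampled = cosampled)
}

#' Empirical CDF and area of a consensus matrix
#'
#' The empirical CDF is taken over the N(N-1)/2 upper-triangular
#' consensus entries; the area is the integral of that step CDF over
#' [0, 1] (sum of step height times step width). Clean two-cluster
#' structure concentrates entries at 0 and 1 and maximizes the area for
#' a given split; diffuse structure places mass at intermediate values.
#'
#' @param M Consensus matrix.
#' @return List with \code{cdf} (a step function of class
#'   \code{"ecdf"}-like closure) and \code{area}.
#' @export
cdfArea <- function(M) {
  n <- nrow(M)
  if (n < 2) stop("consensus CDF requires at least 2 items")
  x <- M[upper.tri(M)]
  m <- length(x)
  xs <- sort(unique(x))
  F <- vapply(xs, function(u) mean(x <= u), 0)
  # integrate the right-continuous step CDF over [0, 1]:
  # sum of (step height) x (width until the next jump or 1)
  area <- sum(vapply(seq_along(xs), function(i) {
    upper <- if (i < length(xs)) xs[i + 1] else 1
    F[i] * (upper - xs[i])
  }, 0))
  cdf <- function(t) vapply(t, function(u) mean(x <= u), 0)
  list(cdf = cdf, area = area)
}

#' Select the number of clusters by the delta-area rule
#'
#' With areas A(k) for contiguous k starting at 2, the relative change is
#' Delta(2) = A(2) and Delta(k) = (A(k) - A(k-1)) / A(k-1) for k > 2.
#' The selected k is the largest k whose relative change exceeds
#' \code{threshold} (strict, so boundary ties keep the smaller, more
#' parsimonious k); if no k qualifies the fallback is 2.
#'
#' @param areas Named numeric vector of CDF areas, names "2", "3", ...
#' @param threshold Relative-change threshold (default 0.10).
#' @return List with \code{selectedK} and the named \code{deltaAreas}.
#' @export
selectK <- function(areas, threshold = 0.10) {
  if (!length(areas)) stop("areas must be non-empty")
  ks <- as.integer(names(areas))
  if (ks[1] != 2 || (length(ks) > 1 && any(diff(ks) != 1)))
    stop("areas must cover contiguous k starting at 2")
  delta <- areas
  delta[1] <- areas[1]
  if (length(areas) > 1)
    delta[-1] <- diff(areas) / areas[-length(areas)]
  qualifying <- ks[delta > threshold]
  sel <- if (length(qualifying)) max(qualifying) else 2L
  list(selectedK = as.integer(sel), deltaAreas = delta)
}

#' Within-cluster consensus diagnostics
#'
#' Mean pairwise consensus among the members of each cluster. A
#' singleton cluster has no pairs and is reported as 1 by convention,
#' with a warning.
#'
#' @param M Consensus matrix.
#' @param labels Integer cluster labels.
#' @return Named numeric vector, one value per cluster.
#' @export
clusterConsensus <- function(M, labels) {
  out <- vapply(sort(unique(labels)), function(c) {
    idx <- which(labels == c)
    if (length(idx) < 2) {
      warning("singleton cluster ", c, "; consensus reported as 1")
      return(1)
    }
    sub <- M[idx, idx]
    mean(sub[upper.tri(sub)])
  }, 0)
  names(out) <- sort(unique(labels))
  out
}

#' Consensus k-means over a range of k
#'
#' Runs [consensusMatrix()] for every k in \code{kRange}, computes CDF
#' areas and the delta-area selection, then produces the final partition
#' by full-data k-means at the selected k together with the
#' within-cluster consensus diagnostics.
#'
#' @param X N x F numeric matrix (or a \linkS4class{PhysioFeatureSet}).
#' @param kRange Contiguous candidate k starting at 2 (default 2:8).
#' @param scheme A [resampleScheme()].
#' @param threshold Delta-area threshold for [selectK()].
#' @return A \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(X, kRange = 2:8, scheme = resampleScheme(),
                             threshold = 0.10) {
  if (is(X, "PhysioFeatureSet")) X <- featureMatrix(X)
  X <- as.matrix(X)
  mats <- list()
  areas <- numeric(0)
  for (k in kRange) {
    M <- consensusMatrix(X, k, scheme)
    mats[[as.character(k)]] <- M
    areas[as.character(k)] <- cdfArea(M)$area
  }
  sel <- selectK(areas, threshold)
  finalLabels <- as.integer(kmeansPartition(X, sel$selectedK,
                                            seed = scheme$baseSeed))
  cc <- clusterConsensus(mats[[as.character(sel$selectedK)]], finalLabels)
  new("ConsensusResult",
      kRange = as.integer(kRange), consensusMatrices = mats,
      areas = areas, deltaAreas = sel$deltaAreas,
      selectedK = sel$selectedK, finalLabels = finalLabels,
      clusterConsensus = cc)
}
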