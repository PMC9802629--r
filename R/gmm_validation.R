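# Gaussian-mixture reproducibility check: diagonal-covariance EM,
# membership-quality summaries and partition agreement (adjusted Rand
# index).

# one EM run from a random initialization; returns NULL on degenerate runs
.emRun <- function(X, k, tol, maxIter, varFloor) {
  n <- nrow(X); F <- ncol(X)
  mu <- X[sample.int(n, k), , drop = FALSE]
  sig2 <- matrix(rep(apply(X, 2, var), each = k), k, F)
  w <- rep(1 / k, k)
  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(maxIter)) {
    # E step in log space
    logDens <- vapply(seq_len(k), function(j) {
      -0.5 * (rowSums(sweep(sweep(X, 2, mu[j, ])^2, 2, sig2[j, ], `/`)) +
                sum(log(2 * pi * sig2[j, ])))
    }, numeric(n))
    logW <- sweep(logDens, 2, log(w), `+`)
    mx <- apply(logW, 1, max)
    lse <- mx + log(rowSums(exp(logW - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logW - lse)
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(NULL)
    w <- nk / n
    mu <- sweep(t(resp) %*% X, 1, nk, `/`)
    for (j in seq_len(k)) {
      d2 <- sweep(X, 2, mu[j, ])^2
      sig2[j, ] <- pmax(colSums(resp[, j] * d2) / nk[j], varFloor)
    }
    if (is.finite(prev) && ll - prev < tol * abs(ll)) break
    prev <- ll
  }
  list(w = w, mu = mu, sig2 = sig2, resp = resp, logLik = ll, trace = trace)
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Expectation-maximization with \code{nStarts} random initializations
#' (component means drawn from the data), keeping the run with the best
#' log-likelihood. Component variances are floored at \code{1e-6} of the
#' per-feature variance to avoid degeneracy. BIC is
#' \eqn{-2 \log L + p \ln N} with \eqn{p = (k - 1) + 2kF} free
#' parameters (weights, means and diagonal variances).
#'
#' @param X N x F numeric matrix or a \linkS4class{PhysioFeatureSet}.
#' @param k Number of components (< N).
#' @param seed Integer seed.
#' @param nStarts Random restarts (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxIter Maximum EM iterations per start.
#' @return A \linkS4class{GmmFit}.
#' @export
fitGmm <- function(X, k, seed = 1L, nStarts = 10L, tol = 1e-8,
                   maxIter = 200L) {
  if (is(X, "PhysioFeatureSet")) X <- featureMatrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("need more observations than components")
  set.seed(seed)
  varFloor <- 1e-6 * mean(apply(X, 2, var))
  best <- NULL
  for (s in seq_len(nStarts)) {
    run <- .emRun(X, k, tol, maxIter, varFloor)
    if (!is.null(run) && (is.null(best) || run$logLik > best$logLik))
      best <- run
  }
  if (is.null(best)) stop("all EM starts degenerated")
  p <- (k - 1) + 2 * k * ncol(X)
  new("GmmFit",
      nComponents = as.integer(k), weights = as.numeric(best$w),
      means = best$mu, variances = best$sig2,
      responsibilities = best$resp, logLik = best$logLik,
      logLikTrace = best$trace,
      bic = -2 * best$logLik + p * log(n))
}

#' Scan the number of mixture components by BIC
#'
#' @param X N x F matrix or \linkS4class{PhysioFeatureSet}.
#' @param kRange Candidate component counts.
#' @param seed Integer seed.
#' @param ... Passed to [fitGmm()].
#' @return List with \code{bic} (named numeric), \code{bestK} and
#'   \code{fits}.
#' @export
scanGmm <- function(X, kRange = 2:8, seed = 1L, ...) {
  fits <- lapply(kRange, function(k) fitGmm(X, k, seed = seed + k, ...))
  bic <- vapply(fits, function(f) f@bic, 0)
  names(bic) <- kRange
  list(bic = bic, bestK = kRange[which.min(bic)],
       fits = setNames(fits, kRange))
}

#' Membership-quality summaries of a mixture fit
#'
#' For each item, its maximum posterior probability (the probability of
#' the component it is assigned to); summaries include the per-cluster
#' median posterior and the fraction of items whose assignment is
#' marginal, defined as a maximum posterior in [0.45, 0.55].
#'
#' @param fit A \linkS4class{GmmFit}.
#' @return List with \code{maxPosterior} (length N), \code{labels},
#'   \code{medianPosterior} (overall), \code{clusterMedian} (per
#'   component) and \code{marginalFraction}.
#' @export
membershipQuality <- function(fit) {
  resp <- fit@responsibilities
  labels <- max.col(resp, ties.method = "first")
  maxPost <- resp[cbind(seq_len(nrow(resp)), labels)]
  clusterMedian <- vapply(seq_len(fit@nComponents), function(j) {
    idx <- labels == j
    if (!any(idx)) NA_real_ else median(maxPost[idx])
  }, 0)
  list(
    maxPosterior = maxPost,
    labels = labels,
    medianPosterior = median(maxPost),
    clusterMedian = clusterMedian,
    marginalFraction = mean(maxPost >= 0.45 & maxPost <= 0.55)
  )
}

#' Compare two partitions: adjusted Rand index and contingency table
#'
#' The adjusted Rand index under the permutation model:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\tfrac12(\sum_i
#' \binom{a_i}{2} + \sum_j \binom{b_j}{2}) - E}} with
#' \eqn{E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}}.
#' 1 means identical partitions, 0 chance-level agreement.
#'
#' @param labelsA,labelsB Two label vectors of equal length.
#' @return List with \code{ari} and \code{table} (the contingency
#'   table).
#' @export
comparePartitions <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  tab <- table(labelsA, labelsB)
  n <- length(labelsA)
  sumij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxIdx <- (a + b) / 2
  ari <- if (maxIdx == expected) {
    if (sumij == expected) 1 else 0  # degenerate (e.g. all-singleton) case
  } else {
    (sumij - expected) / (maxIdx - expected)
  }
  list(ari = ari, table = tab)
}
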