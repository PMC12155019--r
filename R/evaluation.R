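#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table: \deqn{ARI = \frac{\sum_{ab}\binom{n_{ab}}{2} - E}{\tfrac12\left[
#' \sum_a\binom{n_{a\cdot}}{2} + \sum_b\binom{n_{\cdot b}}{2}\right] - E}},
#' \eqn{E = \sum_a\binom{n_{a\cdot}}{2}\sum_b\binom{n_{\cdot b}}{2} /
#' \binom{n}{2}}. Equals 1 iff the partitions are identical (up to label
#' permutation) and has expectation 0 under independent random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return a scalar in `[-1, 1]`.
#' @export
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: permuted labels
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(a)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sumAB <- sum(choose2(tab))
  sumA <- sum(choose2(rowSums(tab)))
  sumB <- sum(choose2(colSums(tab)))
  expected <- sumA * sumB / choose2(n)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)  # both partitions trivial and identical
  (sumAB - expected) / (maxIdx - expected)
}

#' Cross-seed clustering consistency
#'
#' Mean pairwise Adjusted Rand Index over a set of partitions of the same
#' neurons, e.g. MAP labelings from models trained with different seeds.
#'
#' @param partitions list of at least two label vectors of equal length.
#' @return list with `mean` (mean pairwise ARI, diagonal excluded) and
#'   `matrix` (symmetric pairwise ARI matrix with unit diagonal).
#' @export
consistencyAcrossSeeds <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 2L) {
    stop("need at least two partitions", call. = FALSE)
  }
  lens <- lengths(partitions)
  if (length(unique(lens)) != 1L) {
    stop("all partitions must cover the same neuron index set", call. = FALSE)
  }
  m <- length(partitions)
  M <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      M[i, j] <- M[j, i] <- adjustedRandIndex(partitions[[i]],
                                              partitions[[j]])
    }
  }
  list(mean = mean(M[upper.tri(M)]), matrix = M)
}

#' Diagonal-covariance Gaussian mixture baseline
#'
#' The post-hoc clustering baseline: a GMM with diagonal covariance
#' matrices, a `1e-6` floor on every variance (the regularization used
#' with the baseline protocol), free mixing weights, seeded k-means
#' initialization, and EM to convergence. Returns MAP labels.
#'
#' @param Z N x K embedding matrix.
#' @param J number of clusters (N >= J).
#' @param seed integer seed (initialization).
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @return integer label vector of length N.
#' @export
gmmBaseline <- function(Z, J, seed, maxIter = 200L, tol = 1e-8) {
  Z <- as.matrix(Z)
  N <- nrow(Z); K <- ncol(Z)
  if (N < J) stop("fewer points than clusters", call. = FALSE)
  floorVar <- 1e-6
  km <- withStream(seed, "gmm-init",
                   stats::kmeans(Z, J, nstart = 10L, iter.max = 100L))
  mu <- unname(km$centers)
  sig <- matrix(0, J, K)
  for (j in seq_len(J)) {
    sig[j, ] <- pmax(colMeans((t(t(Z[km$cluster == j, , drop = FALSE])
                                 - mu[j, ]))^2), floorVar)
  }
  mixw <- pmax(km$size / N, 1e-12)
  prevLL <- -Inf
  logR <- NULL
  for (it in seq_len(maxIter)) {
    logR <- matrix(0, N, J)
    for (j in seq_len(J)) {
      logR[, j] <- log(mixw[j]) - sum(log(2 * pi * sig[j, ])) / 2 -
        colSums((t(Z) - mu[j, ])^2 / sig[j, ]) / 2
    }
    norm <- rowLogSumExp(logR)
    ll <- sum(norm)
    R <- exp(logR - norm)
    nk <- pmax(colSums(R), 1e-12)
    mixw <- nk / N
    mu <- crossprod(R, Z) / nk
    for (j in seq_len(J)) {
      sig[j, ] <- pmax(colSums(R[, j] * t(t(Z) - mu[j, ])^2) / nk[j],
                       floorVar)
    }
    if (ll - prevLL < tol && ll >= prevLL) break
    prevLL <- ll
  }
  mapAssign(exp(logR - rowLogSumExp(logR)))
}

#' k-means baseline
#'
#' Single-start seeded k-means (its sensitivity to initialization is part
#' of what the consistency comparison surfaces, so restarts are not
#' hidden behind the seed).
#'
#' @inheritParams gmmBaseline
#' @return integer label vector.
#' @export
kmeansBaseline <- function(Z, J, seed) {
  Z <- as.matrix(Z)
  if (nrow(Z) < J) stop("fewer points than clusters", call. = FALSE)
  withStream(seed, "kmeans-baseline",
             stats::kmeans(Z, J, nstart = 1L, iter.max = 100L))$cluster
}

#' Confusion matrix with optimally matched columns
#'
#' Builds the contingency table of predicted vs true labels and permutes
#' the predicted-label rows so the trace (number of agreeing pairs) is
#' maximal, by exhaustive search over permutations (predicted label count
#' must be <= 8).
#'
#' @param pred,truth label vectors of equal length.
#' @return a matrix with matched predicted labels in rows, true labels in
#'   columns; `attr(, "permutation")` records the applied row order.
#' @export
alignAndConfuse <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  tab <- unclass(table(pred, truth))
  k <- nrow(tab)
  if (k > 8L) stop("exhaustive matching supports at most 8 predicted labels",
                   call. = FALSE)
  perms <- permutations(k)
  best <- perms[[1L]]
  bestTrace <- -Inf
  d <- min(nrow(tab), ncol(tab))
  for (p in perms) {
    tr <- sum(diag(tab[p, , drop = FALSE][seq_len(d), seq_len(d),
                                          drop = FALSE]))
    if (tr > bestTrace) {
      bestTrace <- tr
      best <- p
    }
  }
  out <- tab[best, , drop = FALSE]
  attr(out, "permutation") <- best
  out
}

permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Mean per-neuron response correlation
#'
#' Pearson correlation between predicted and observed responses across
#' trials, computed per neuron and averaged over neurons. Neurons with
#' constant predicted or observed responses are excluded with a warning.
#'
#' @param predicted,observed B x N matrices (B >= 2).
#' @return scalar mean correlation.
#' @export
meanNeuronCorrelation <- function(predicted, observed) {
  if (!identical(dim(predicted), dim(observed))) {
    stop("'predicted' and 'observed' must have identical shape", call. = FALSE)
  }
  if (nrow(predicted) < 2L) stop("need at least two trials", call. = FALSE)
  sdP <- apply(predicted, 2L, stats::sd)
  sdO <- apply(observed, 2L, stats::sd)
  keep <- sdP > 0 & sdO > 0
  if (!any(keep)) stop("all neurons are constant", call. = FALSE)
  if (!all(keep)) {
    warning(sprintf("excluding %d constant neuron(s) from the correlation",
                    sum(!keep)))
  }
  cors <- vapply(which(keep), function(i) {
    stats::cor(predicted[, i], observed[, i])
  }, numeric(1))
  mean(cors)
}
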