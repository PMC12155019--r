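#' Log-density of a multivariate Student's t-distribution (diagonal scale)
#'
#' Evaluates \deqn{\log f_t(z;\mu,\Sigma,\nu) =
#'   \log\Gamma\!\left(\tfrac{\nu+K}{2}\right) - \log\Gamma\!\left(\tfrac{\nu}{2}\right)
#'   - \tfrac{K}{2}\log(\nu\pi) - \tfrac12\sum_k\log\sigma^2_k
#'   - \tfrac{\nu+K}{2}\log\!\left(1 + \delta/\nu\right)}
#' with Mahalanobis distance \eqn{\delta = \sum_k (z_k-\mu_k)^2/\sigma^2_k},
#' entirely in log space. As \eqn{\nu \to \infty} this approaches the
#' diagonal-Gaussian log-density.
#'
#' @param z numeric K-vector (or N x K matrix: one row per point).
#' @param center numeric K-vector \eqn{\mu}.
#' @param scaleDiag numeric K-vector of strictly positive \eqn{\sigma^2_k}.
#' @param dof degrees of freedom \eqn{\nu > 0}.
#' @return numeric log-density, one value per row of `z`.
#' @export
#' @examples
#' tLogDensity(c(1, 2), center = c(0, 0), scaleDiag = c(1, 4), dof = 2.1)
tLogDensity <- function(z, center, scaleDiag, dof) {
  if (any(scaleDiag <= 0)) {
    stop("scale matrix diagonal must be strictly positive", call. = FALSE)
  }
  if (length(dof) != 1L || dof <= 0) stop("'dof' must be a positive scalar",
                                          call. = FALSE)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  K <- ncol(z)
  stopifnot(length(center) == K, length(scaleDiag) == K)
  delta <- colSums((t(z) - center)^2 / scaleDiag)
  lgamma((dof + K) / 2) - lgamma(dof / 2) - (K / 2) * log(dof * pi) -
    sum(log(scaleDiag)) / 2 - ((dof + K) / 2) * log1p(delta / dof)
}

# N x J matrices of log t-densities and Mahalanobis distances of the rows of
# Z under every component of `state`
componentLogDensities <- function(Z, state) {
  Z <- as.matrix(Z)
  J <- nrow(state@centers)
  K <- ncol(state@centers)
  if (ncol(Z) != K) {
    stop(sprintf("embeddings have %d columns but the mixture state has %d",
                 ncol(Z), K), call. = FALSE)
  }
  nu <- state@dof
  logf <- delta <- matrix(0, nrow(Z), J)
  const <- lgamma((nu + K) / 2) - lgamma(nu / 2) - (K / 2) * log(nu * pi)
  for (j in seq_len(J)) {
    d <- colSums((t(Z) - state@centers[j, ])^2 / state@scaleDiags[j, ])
    delta[, j] <- d
    logf[, j] <- const - sum(log(state@scaleDiags[j, ])) / 2 -
      ((nu + K) / 2) * log1p(d / nu)
  }
  list(logf = logf, delta = delta)
}

#' E-step: soft assignments and latent scales
#'
#' Computes the responsibilities
#' \deqn{q_{ij} = \frac{f_t(z_i;\mu_j,\Sigma_j,\nu)}
#'                     {\sum_{j'} f_t(z_i;\mu_{j'},\Sigma_{j'},\nu)}}
#' via log-sum-exp (mixing weights are fixed at `1/J` and cancel), and the
#' latent gamma scaling factors of the shape-rate representation
#' \deqn{u_{ij} = \frac{\nu + K}{\nu + (z_i-\mu_j)^\top\Sigma_j^{-1}(z_i-\mu_j)}.}
#'
#' @param Z N x K embedding matrix.
#' @param state a [TMixtureState-class].
#' @return list with components `Q` (N x J row-stochastic matrix) and
#'   `U` (N x J positive matrix).
#' @export
#' @examples
#' st <- tMixtureState(rbind(0, 5), rbind(1, 1))
#' eStep(matrix(c(0.1, 4.9), ncol = 1), st)
eStep <- function(Z, state) {
  cd <- componentLogDensities(Z, state)
  logQ <- cd$logf - rowLogSumExp(cd$logf)
  K <- ncol(state@centers)
  list(Q = exp(logQ), U = (state@dof + K) / (state@dof + cd$delta))
}

#' M-step: closed-form update of centers and scale diagonals
#'
#' Updates each cluster center as the (q u)-weighted mean of the
#' embeddings, \deqn{\mu_j = \sum_i q_{ij} u_{ij} z_i / \sum_i q_{ij} u_{ij},}
#' and each diagonal scale entry as
#' \deqn{\Sigma_{jk} = \sum_i q_{ij} u_{ij} (z_{ik}-\mu_{jk})^2 / \sum_i q_{ij},}
#' using the freshly updated center. Every scale entry is then clamped from
#' below at the state's `clampFloor` — the heuristic guard against
#' ill-conditioned scale matrices in high dimensions.
#'
#' @param Z N x K embedding matrix.
#' @param Q N x J soft assignments from [eStep()].
#' @param U N x J latent scales from [eStep()].
#' @param state the current [TMixtureState-class].
#' @return the updated [TMixtureState-class].
#' @export
mStep <- function(Z, Q, U, state) {
  Z <- as.matrix(Z)
  J <- nrow(state@centers)
  stopifnot(nrow(Q) == nrow(Z), ncol(Q) == J, identical(dim(Q), dim(U)))
  qcol <- colSums(Q)
  if (any(qcol == 0)) {
    stop(sprintf("degenerate cluster(s) with zero total responsibility: %s",
                 paste(which(qcol == 0), collapse = ", ")), call. = FALSE)
  }
  QU <- Q * U
  centers <- crossprod(QU, Z) / colSums(QU)
  scaleDiags <- matrix(0, J, ncol(Z))
  for (j in seq_len(J)) {
    dev2 <- (t(Z) - centers[j, ])^2
    scaleDiags[j, ] <- colSums(t(dev2) * QU[, j]) / qcol[j]
  }
  scaleDiags <- pmax(scaleDiags, state@clampFloor)
  new("TMixtureState", centers = centers, scaleDiags = scaleDiags,
      dof = state@dof, clampFloor = state@clampFloor)
}

#' Sharpened target distribution
#'
#' Squares the soft assignments and renormalizes by cluster frequency:
#' \deqn{p_{ij} = \frac{q_{ij}^2/f_j}{\sum_{j'} q_{ij'}^2/f_{j'}}, \qquad
#'       f_j = \sum_i q_{ij}.}
#' Squaring strengthens confident assignments; dividing by \eqn{f_j}
#' prevents large clusters from dominating the loss.
#'
#' @param Q N x J row-stochastic soft-assignment matrix.
#' @return list with `P` (N x J row-stochastic target) and
#'   `clusterFrequencies` (the \eqn{f_j}).
#' @export
#' @examples
#' targetDistribution(rbind(c(0.8, 0.2), c(0.6, 0.4)))
targetDistribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  if (any(f == 0)) {
    stop(sprintf("empty cluster(s): column(s) %s of Q sum to 0",
                 paste(which(f == 0), collapse = ", ")), call. = FALSE)
  }
  W <- sweep(Q^2, 2L, f, "/")
  list(P = W / rowSums(W), clusterFrequencies = f)
}

#' Clustering loss: KL divergence of Q from the sharpened target P
#'
#' Returns \eqn{\sum_i \sum_j p_{ij} \log(p_{ij}/q_{ij})} with the usual
#' convention \eqn{0 \log(0/q) = 0}. The target is treated as a constant:
#' during training it is recomputed from Q each batch and no gradient flows
#' through it. When all cluster centers and scales coincide, Q and P are
#' both uniform and the loss is exactly 0 — the degenerate optimum that
#' makes fixed-scale deep embedding clustering collapse.
#'
#' @param Q N x J row-stochastic soft assignments.
#' @param P N x J row-stochastic target (e.g. from [targetDistribution()]).
#' @return nonnegative scalar (`Inf`, with a warning, if some `q = 0` where
#'   `p > 0`).
#' @export
clusteringLoss <- function(Q, P) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  stopifnot(identical(dim(Q), dim(P)))
  pos <- P > 0
  if (any(Q[pos] == 0)) {
    warning("q = 0 where p > 0: KL divergence is infinite")
    return(Inf)
  }
  sum(P[pos] * (log(P[pos]) - log(Q[pos])))
}

#' Initialize a mixture state with k-means
#'
#' Cluster centers are set to seeded k-means centroids (10 restarts, best
#' within-cluster sum of squares wins) and scale diagonals to the
#' per-dimension variance of each k-means cluster's members, clamped at
#' `clampFloor`. Empty k-means clusters trigger a reseeded retry.
#'
#' @param Z N x K embedding matrix.
#' @param J number of clusters (N >= J required).
#' @param seed integer seed for k-means.
#' @param dof degrees of freedom of the returned state; default 2.1.
#' @param clampFloor scale floor; default `1e-6`.
#' @param nstart number of k-means restarts; default 10.
#' @param maxRetries reseeded retries on an empty cluster; default 5.
#' @return a [TMixtureState-class].
#' @export
initClusters <- function(Z, J, seed, dof = 2.1, clampFloor = 1e-6,
                         nstart = 10L, maxRetries = 5L) {
  Z <- as.matrix(Z)
  if (nrow(Z) < J) {
    stop(sprintf("need at least J = %d embeddings, got %d", J, nrow(Z)),
         call. = FALSE)
  }
  km <- NULL
  for (attempt in seq_len(maxRetries)) {
    km <- withStream(seed + attempt - 1L, "kmeans", {
      tryCatch(
        stats::kmeans(Z, centers = J, nstart = nstart, iter.max = 100L),
        error = function(e) NULL)
    })
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) {
    stop("k-means failed to produce non-empty clusters after retries",
         call. = FALSE)
  }
  scaleDiags <- matrix(0, J, ncol(Z))
  for (j in seq_len(J)) {
    member <- Z[km$cluster == j, , drop = FALSE]
    v <- colMeans((t(t(member) - km$centers[j, ]))^2)
    scaleDiags[j, ] <- pmax(v, clampFloor)
  }
  new("TMixtureState", centers = unname(km$centers), scaleDiags = scaleDiags,
      dof = dof, clampFloor = clampFloor)
}

#' Log-likelihood of embeddings under the equal-weight t-mixture
#'
#' \deqn{\ell(Z) = \sum_i \log\left[\frac1J \sum_j f_t(z_i;\mu_j,\Sigma_j,\nu)\right]}
#' computed via log-sum-exp. With fixed \eqn{\nu} and equal mixing
#' weights, one E-step followed by one M-step never decreases this value
#' (unless the scale clamp intervenes).
#'
#' @inheritParams eStep
#' @return scalar log-likelihood.
#' @export
mixtureLogLik <- function(Z, state) {
  cd <- componentLogDensities(Z, state)
  sum(rowLogSumExp(cd$logf) - log(nrow(state@centers)))
}

#' MAP cluster assignment
#'
#' @param Q N x J soft-assignment matrix.
#' @return integer vector of labels in `1..J`; ties break toward the lowest
#'   cluster index.
#' @export
mapAssign <- function(Q) {
  Q <- as.matrix(Q)
  as.integer(apply(Q, 1L, which.max))
}

#' Fit the t-mixture to a fixed embedding matrix by EM alone
#'
#' Alternates [eStep()] and [mStep()] on fixed embeddings. Clusters whose
#' total responsibility drops below `1e-8 * N` are re-initialized at the
#' embedding with the lowest maximum responsibility (with a warning).
#'
#' @param Z N x K embedding matrix.
#' @param J number of clusters.
#' @param seed integer seed (k-means init).
#' @param iters number of EM cycles; default 100.
#' @param dof,clampFloor passed to [initClusters()].
#' @param tol stop early when the log-likelihood improves by less than this;
#'   default `1e-8`.
#' @return list with `state`, `Q`, `U`, `labels`, `logLik` (trace).
#' @export
#' @examples
#' set.seed(1)
#' Z <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 6), 50))
#' fit <- emFit(Z, J = 2, seed = 1, iters = 25)
#' table(fit$labels)
emFit <- function(Z, J, seed, iters = 100L, dof = 2.1, clampFloor = 1e-6,
                  tol = 1e-8) {
  Z <- as.matrix(Z)
  state <- initClusters(Z, J, seed, dof = dof, clampFloor = clampFloor)
  ll <- numeric(0)
  es <- NULL
  for (it in seq_len(iters)) {
    es <- eStep(Z, state)
    state <- refreshEmptyClusters(Z, es$Q, state)
    state <- mStep(Z, es$Q, es$U, state)
    ll <- c(ll, mixtureLogLik(Z, state))
    if (it > 1L && ll[it] - ll[it - 1L] < tol && ll[it] >= ll[it - 1L]) break
  }
  es <- eStep(Z, state)
  list(state = state, Q = es$Q, U = es$U, labels = mapAssign(es$Q),
       logLik = ll)
}

# empty-cluster policy: responsibilities below 1e-8 * N move the center to
# the least-claimed embedding and reset that cluster's scale
refreshEmptyClusters <- function(Z, Q, state) {
  qcol <- colSums(Q)
  starved <- which(qcol < 1e-8 * nrow(Z))
  if (!length(starved)) return(state)
  warning(sprintf("re-initializing starved cluster(s) %s",
                  paste(starved, collapse = ", ")))
  centers <- state@centers
  scaleDiags <- state@scaleDiags
  loner <- order(apply(Q, 1L, max))
  for (k in seq_along(starved)) {
    centers[starved[k], ] <- Z[loner[k], ]
    scaleDiags[starved[k], ] <- pmax(apply(Z, 2L, stats::var),
                                     state@clampFloor)
  }
  new("TMixtureState", centers = centers, scaleDiags = scaleDiags,
      dof = state@dof, clampFloor = state@clampFloor)
}
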