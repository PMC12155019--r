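#' t-SNE embedding of the functional embeddings
#'
#' Exact (O(N^2)) t-SNE for figure use, following the large-embedding
#' visualization guidelines used throughout the package: perplexity
#' `N/100`, an early-exaggeration phase with factor `N/10` at learning
#' rate 1 (the exaggeration factor acts as the effective attraction step
#' size), followed by a standard phase without exaggeration at learning
#' rate `N/12`. Standard momentum (0.5 in the early phase, 0.8 after)
#' and per-coordinate gain adaptation.
#'
#' Intended for visualization only; no quantitative metric in the package
#' consumes t-SNE coordinates.
#'
#' @param Z N x K embedding matrix with N >= 300 (so the default
#'   perplexity N/100 is meaningful).
#' @param seed integer seed for the random initialization.
#' @param perplexity target perplexity; default `N/100`.
#' @param learningRate step size of the early-exaggeration phase;
#'   default 1.
#' @param earlyExaggeration factor applied to the attractive forces in
#'   the early phase; default `N/10`.
#' @param lateLearningRate step size after exaggeration ends; default
#'   `N/12`.
#' @param iters total gradient iterations (the first 30% run with
#'   exaggeration); default 750.
#' @return N x 2 coordinate matrix.
#' @export
tsneEmbed <- function(Z, seed, perplexity = NULL, learningRate = 1,
                      earlyExaggeration = NULL, lateLearningRate = NULL,
                      iters = 750L) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  if (N < 300L) {
    stop("need at least 300 points for the default perplexity N/100",
         call. = FALSE)
  }
  if (is.null(perplexity)) perplexity <- N / 100
  if (is.null(earlyExaggeration)) earlyExaggeration <- N / 10
  if (is.null(lateLearningRate)) lateLearningRate <- N / 12
  if (perplexity < 2 || 3 * perplexity >= N) {
    stop("perplexity out of range for this N", call. = FALSE)
  }
  D2 <- as.matrix(stats::dist(Z))^2
  P <- condPerplexityMatrix(D2, perplexity)
  P <- (P + t(P)) / (2 * N)
  P <- pmax(P, 1e-12)
  exaggerationEnd <- max(1L, floor(iters * 0.3))
  Y <- withStream(seed, "tsne", matrix(stats::rnorm(N * 2, sd = 1e-4), N, 2L))
  vel <- matrix(0, N, 2L)
  gains <- matrix(1, N, 2L)
  for (it in seq_len(iters)) {
    early <- it <= exaggerationEnd
    ex <- if (early) earlyExaggeration else 1
    lr <- if (early) learningRate else lateLearningRate
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Qm <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Qm) * num
    grad <- 4 * (rowSums(W) * Y - W %*% Y)
    mom <- if (early) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(vel),
                               gains + 0.2, gains * 0.8))
    vel <- mom * vel - lr * gains * grad
    Y <- Y + vel
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

# per-point Gaussian bandwidth calibration: binary search on the
# precision so each row of the conditional distribution has the target
# perplexity
condPerplexityMatrix <- function(D2, perplexity, tol = 1e-5, maxIter = 60L) {
  N <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(maxIter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - target) < tol) break
      if (h > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P
}
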