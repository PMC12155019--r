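# Independent oracles used across the suite: naive-loop implementations
# and quadrature, kept deliberately separate from the package's own code
# paths.

# t density by 1-d adaptive quadrature over the latent gamma scale of the
# shape-rate representation: integral of N(z; mu, sigma/u) Gamma(u; nu/2, nu/2)
oracleTDensityQuad <- function(z, mu, sig, nu) {
  integrand <- function(u) {
    vapply(u, function(ui) {
      exp(sum(stats::dnorm(z, mu, sqrt(sig / ui), log = TRUE)) +
            stats::dgamma(ui, nu / 2, rate = nu / 2, log = TRUE))
    }, numeric(1))
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
}

# naive-loop E-step (no log-sum-exp, explicit density formula)
oracleEStep <- function(Z, centers, scales, nu) {
  N <- nrow(Z); J <- nrow(centers); K <- ncol(Z)
  f <- matrix(0, N, J); U <- matrix(0, N, J)
  for (i in seq_len(N)) {
    for (j in seq_len(J)) {
      d <- 0
      for (k in seq_len(K)) d <- d + (Z[i, k] - centers[j, k])^2 / scales[j, k]
      f[i, j] <- gamma((nu + K) / 2) / gamma(nu / 2) / (nu * pi)^(K / 2) /
        sqrt(prod(scales[j, ])) * (1 + d / nu)^(-(nu + K) / 2)
      U[i, j] <- (nu + K) / (nu + d)
    }
  }
  list(Q = f / rowSums(f), U = U)
}

# naive-loop M-step
oracleMStep <- function(Z, Q, U) {
  N <- nrow(Z); J <- ncol(Q); K <- ncol(Z)
  centers <- matrix(0, J, K); scales <- matrix(0, J, K)
  for (j in seq_len(J)) {
    num <- rep(0, K); den <- 0; qsum <- 0
    for (i in seq_len(N)) {
      num <- num + Q[i, j] * U[i, j] * Z[i, ]
      den <- den + Q[i, j] * U[i, j]
      qsum <- qsum + Q[i, j]
    }
    centers[j, ] <- num / den
    s <- rep(0, K)
    for (i in seq_len(N)) {
      s <- s + Q[i, j] * U[i, j] * (Z[i, ] - centers[j, ])^2
    }
    scales[j, ] <- s / qsum
  }
  list(centers = centers, scales = scales)
}

# direct two-loop target distribution
oracleTargetDistribution <- function(Q) {
  f <- colSums(Q)
  P <- matrix(0, nrow(Q), ncol(Q))
  for (i in seq_len(nrow(Q))) {
    w <- Q[i, ]^2 / f
    P[i, ] <- w / sum(w)
  }
  P
}

# brute-force KL sum
oracleKL <- function(Q, P) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) s <- s + P[i, j] * log(P[i, j] / Q[i, j])
    }
  }
  s
}

# pair-counting Adjusted Rand Index: agreement over all n(n-1)/2 pairs
oracleARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxIdx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxIdx == expected) return(1)
  (n11 - expected) / (maxIdx - expected)
}

# all set partitions of 1..n as label vectors
allPartitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPartitions(n - 1L)) {
    for (lab in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, lab)
    }
  }
  out
}

# 4-corner bilinear interpolation oracle for a single position
oracleBilinear <- function(fm, position) {
  H <- dim(fm)[1L]; W <- dim(fm)[2L]
  gx <- (position[1L] + 1) / 2 * (W - 1)
  gy <- (position[2L] + 1) / 2 * (H - 1)
  x0 <- min(max(floor(gx), 0), max(W - 2, 0)); ax <- gx - x0
  y0 <- min(max(floor(gy), 0), max(H - 2, 0)); ay <- gy - y0
  x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
  (1 - ax) * (1 - ay) * fm[y0 + 1, x0 + 1, ] +
    ax * (1 - ay) * fm[y0 + 1, x1 + 1, ] +
    (1 - ax) * ay * fm[y1 + 1, x0 + 1, ] +
    ax * ay * fm[y1 + 1, x1 + 1, ]
}

# small well-separated embedding cloud with labels
makeBlobs <- function(n = 60, K = 2, centers = rbind(c(0, 0), c(6, 6)),
                      sd = 0.3, seed = 1) {
  set.seed(seed)
  J <- nrow(centers)
  lab <- rep(seq_len(J), length.out = n)
  Z <- centers[lab, , drop = FALSE] + matrix(rnorm(n * K, sd = sd), n, K)
  list(Z = Z, labels = lab)
}

# miniature toy spec for fast training tests (same geometry, smaller)
miniToySpec <- function(seed = 1) {
  toySpec(nStimuli = 400L, dim = 10L, groupSizes = c(80L, 20L),
          groupCenters = c(1, 1.5), noiseHalfWidths = c(1 / 300, 1 / 120),
          seed = seed)
}
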