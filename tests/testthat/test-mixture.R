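test_that("t log-density matches quadrature over the latent gamma scale", {
  v <- tLogDensity(c(1, 2), center = c(0, 0), scaleDiag = c(1, 4), dof = 2.1)
  expect_equal(exp(v), oracleTDensityQuad(c(1, 2), c(0, 0), c(1, 4), 2.1),
               tolerance = 1e-6)
  set.seed(4)
  for (rep in 1:5) {
    K <- sample(1:4, 1)
    z <- rnorm(K); mu <- rnorm(K); sig <- runif(K, 0.2, 3)
    nu <- runif(1, 2.05, 8)
    expect_equal(exp(tLogDensity(z, mu, sig, nu)),
                 oracleTDensityQuad(z, mu, sig, nu), tolerance = 1e-6)
  }
})

test_that("t density peaks at its center and approaches the Gaussian limit", {
  set.seed(1)
  mu <- rnorm(3); sig <- runif(3, 0.5, 2)
  atCenter <- tLogDensity(mu, mu, sig, 2.1)
  for (rep in 1:10) {
    expect_gt(atCenter, tLogDensity(mu + rnorm(3, sd = 0.5), mu, sig, 2.1))
  }
  z <- seq(-3, 3, by = 0.5)
  expect_equal(tLogDensity(matrix(z), 0, 1, 1e6),
               dnorm(z, log = TRUE), tolerance = 1e-4)
  # density values themselves agree within 1e-4 relative at nu = 1e6
  expect_equal(exp(tLogDensity(matrix(c(0, 1, 2)), 0, 1, 1e6)),
               dnorm(c(0, 1, 2)), tolerance = 1e-4)
})

test_that("t log-density rejects invalid scale and dof", {
  expect_error(tLogDensity(0, 0, -1, 2.1), "positive")
  expect_error(tLogDensity(0, 0, 1, 0), "dof")
})

test_that("E-step and M-step match naive-loop oracles on small instances", {
  set.seed(11)
  for (rep in 1:5) {
    N <- sample(4:10, 1); K <- sample(1:3, 1); J <- sample(2:3, 1)
    Z <- matrix(rnorm(N * K, sd = 2), N, K)
    centers <- matrix(rnorm(J * K), J, K)
    scales <- matrix(runif(J * K, 0.3, 2), J, K)
    nu <- 2.1
    st <- tMixtureState(centers, scales, dof = nu, clampFloor = 1e-12)
    es <- eStep(Z, st)
    or <- oracleEStep(Z, centers, scales, nu)
    expect_equal(es$Q, or$Q, tolerance = 1e-10)
    expect_equal(es$U, or$U, tolerance = 1e-10)
    st2 <- mStep(Z, es$Q, es$U, st)
    om <- oracleMStep(Z, es$Q, es$U)
    expect_equal(centers(st2), om$centers, tolerance = 1e-10)
    expect_equal(scaleDiags(st2), pmax(om$scales, 1e-12), tolerance = 1e-10)
    expect_true(all(abs(rowSums(es$Q) - 1) < 1e-9))
  }
})

test_that("latent scales hit (nu+K)/nu at the center and Q is dominated by a near cluster", {
  K <- 30
  st <- tMixtureState(rbind(rep(0, K), rep(100, K)),
                      rbind(rep(1, K), rep(1, K)), dof = 2.1)
  es <- eStep(matrix(0, 1, K), st)
  expect_equal(es$U[1, 1], 32.1 / 2.1, tolerance = 1e-12)
  expect_gt(es$Q[1, 1], 1 - 1e-6)
})

test_that("identical components yield uniform Q and zero KL (degenerate optimum)", {
  set.seed(5)
  for (J in 2:4) {
    Z <- matrix(rnorm(40), 20, 2)
    st <- tMixtureState(matrix(1, J, 2), matrix(0.5, J, 2))
    es <- eStep(Z, st)
    expect_equal(es$Q, matrix(1 / J, 20, J), tolerance = 1e-12)
    td <- targetDistribution(es$Q)
    expect_equal(td$P, matrix(1 / J, 20, J), tolerance = 1e-12)
    expect_lt(abs(clusteringLoss(es$Q, td$P)), 1e-12)
  }
})

test_that("target distribution matches the direct formula and sharpens confidence", {
  Q <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  td <- targetDistribution(Q)
  expect_equal(td$P, oracleTargetDistribution(Q), tolerance = 1e-12)
  expect_equal(td$clusterFrequencies, colSums(Q))
  expect_gt(td$P[1, 1], Q[1, 1])
  # one-hot rows are fixed points
  Qh <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(targetDistribution(Qh)$P, Qh)
  expect_error(targetDistribution(rbind(c(1, 0), c(1, 0))), "empty")
  set.seed(2)
  Qr <- matrix(rexp(60), 20, 3); Qr <- Qr / rowSums(Qr)
  expect_true(all(abs(rowSums(targetDistribution(Qr)$P) - 1) < 1e-9))
})

test_that("clustering loss is the displayed p*log(p/q) sum, zero iff P = Q", {
  expect_identical(clusteringLoss(rbind(c(0.3, 0.7)), rbind(c(0.3, 0.7))), 0)
  Q <- rbind(c(0.8, 0.2)); P <- rbind(c(0.9, 0.1))
  expect_equal(clusteringLoss(Q, P), oracleKL(Q, P), tolerance = 1e-12)
  expect_gt(clusteringLoss(Q, P), 0)
  # 0 * log(0/q) treated as 0; q = 0 under p > 0 is an infinite loss
  expect_equal(clusteringLoss(rbind(c(0.5, 0.5)), rbind(c(1, 0))),
               oracleKL(rbind(c(0.5, 0.5)), rbind(c(1, 0))))
  expect_warning(v <- clusteringLoss(rbind(c(1, 0)), rbind(c(0.5, 0.5))),
                 "infinite")
  expect_identical(v, Inf)
})

test_that("k-means initialization is deterministic and clamps point-mass scales", {
  Z <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  st <- initClusters(Z, 2, seed = 3)
  expect_equal(sort(as.vector(centers(st))), c(0, 1))
  expect_equal(as.vector(scaleDiags(st)), rep(1e-6, 2))
  st2 <- initClusters(Z, 2, seed = 3)
  expect_identical(centers(st), centers(st2))
  expect_identical(scaleDiags(st), scaleDiags(st2))
  expect_error(initClusters(matrix(1, 1, 1), 2, seed = 1), "at least")
})

test_that("k-means initialization lands on the toy group means", {
  ds <- genToyLinear(miniToySpec(seed = 8))
  st <- initClusters(trueWeights(ds), 2, seed = 1)
  ord <- order(centers(st)[, 1])
  expect_true(all(abs(centers(st)[ord[1], ] - 1) < 0.05))
  expect_true(all(abs(centers(st)[ord[2], ] - 1.5) < 0.05))
})

test_that("mixture log-likelihood reduces to the single-component density sum", {
  set.seed(7)
  Z <- matrix(rnorm(12), 6, 2)
  st <- tMixtureState(matrix(0, 1, 2), matrix(1, 1, 2))
  expect_equal(mixtureLogLik(Z, st),
               sum(tLogDensity(Z, c(0, 0), c(1, 1), 2.1)), tolerance = 1e-12)
  # N = 2, K = 1 instance against the quadrature oracle
  Z1 <- matrix(c(-0.3, 1.2), 2, 1)
  st2 <- tMixtureState(rbind(0, 1), rbind(0.8, 1.5), dof = 2.1)
  byHand <- sum(log(0.5 * (
    vapply(Z1[, 1], oracleTDensityQuad, numeric(1), mu = 0, sig = 0.8, nu = 2.1) +
    vapply(Z1[, 1], oracleTDensityQuad, numeric(1), mu = 1, sig = 1.5, nu = 2.1))))
  expect_equal(mixtureLogLik(Z1, st2), byHand, tolerance = 1e-6)
})

test_that("an E/M cycle never decreases the mixture log-likelihood", {
  set.seed(21)
  for (rep in 1:20) {
    N <- 40; K <- sample(2:3, 1); J <- 2
    Z <- matrix(rnorm(N * K, sd = 2), N, K)
    st <- tMixtureState(matrix(rnorm(J * K), J, K),
                        matrix(runif(J * K, 0.5, 2), J, K),
                        dof = 2.1, clampFloor = 1e-300)
    ll <- mixtureLogLik(Z, st)
    for (it in 1:50) {
      es <- eStep(Z, st)
      st <- mStep(Z, es$Q, es$U, st)
      llNew <- mixtureLogLik(Z, st)
      expect_gte(llNew, ll - 1e-8)
      ll <- llNew
    }
  }
})

test_that("MAP assignment takes the argmax with low-index ties", {
  expect_identical(mapAssign(rbind(c(0.9, 0.1))), 1L)
  expect_identical(mapAssign(rbind(c(0.5, 0.5))), 1L)
  expect_identical(mapAssign(rbind(c(0.2, 0.3, 0.5), c(0.4, 0.4, 0.2))),
                   c(3L, 1L))
  Qh <- diag(3)[c(2, 1, 3, 2), ]
  expect_identical(mapAssign(Qh), c(2L, 1L, 3L, 2L))
})

test_that("EM-only fitting recovers planted t-mixture structure", {
  truth <- tMixtureState(rbind(rep(0, 5), rep(5 / sqrt(5), 5)),
                         matrix(1, 2, 5), dof = 2.1)
  draw <- genTMMSamples(truth, 2000, seed = 31)
  fit <- emFit(draw$samples, J = 2, seed = 31, iters = 60)
  ord <- order(centers(fit$state)[, 1])
  expect_true(max(abs(centers(fit$state)[ord[1], ] - 0)) < 0.15)
  expect_true(max(abs(centers(fit$state)[ord[2], ] - 5 / sqrt(5))) < 0.15)
  # the EM MAP rule agrees with the true-parameter MAP rule up to the
  # overlap the heavy tails impose (no estimator can undo tail overlap)
  esTrue <- eStep(draw$samples, truth)
  bayes <- mapAssign(esTrue$Q)
  expect_gt(adjustedRandIndex(fit$labels, bayes), 0.95)
  expect_gt(adjustedRandIndex(fit$labels, draw$labels), 0.7)
})

test_that("degenerate clusters raise errors naming the cluster", {
  Z <- matrix(rnorm(10), 5, 2)
  st <- tMixtureState(matrix(0, 2, 2), matrix(1, 2, 2))
  Q <- cbind(rep(1, 5), rep(0, 5))
  expect_error(mStep(Z, Q, Q + 1, st), "2")
})
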