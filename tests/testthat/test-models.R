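test_that("linear prediction is the inner product of weights and stimuli", {
  m <- linearNeuronModel(weights = diag(3))
  expect_equal(linearPredict(m, diag(3)), diag(3))
  # an all-ones 30-d neuron responds with 30 to an all-ones stimulus
  m1 <- linearNeuronModel(weights = matrix(1, 1, 30))
  expect_equal(as.numeric(linearPredict(m1, matrix(1, 1, 30))), 30)
  set.seed(3)
  Z <- matrix(rnorm(12), 4, 3); X <- matrix(rnorm(15), 5, 3)
  pred <- linearPredict(linearNeuronModel(weights = Z), X)
  naive <- matrix(0, 5, 4)
  for (b in 1:5) for (i in 1:4) naive[b, i] <- sum(Z[i, ] * X[b, ])
  expect_equal(pred, naive, tolerance = 1e-12)
  expect_error(linearPredict(m, matrix(0, 2, 4)), "columns")
})

test_that("MSE loss and its analytic weight gradient are correct", {
  expect_identical(mseLoss(diag(2), diag(2)), 0)
  expect_equal(mseLoss(matrix(3, 2, 2), matrix(1, 2, 2)), 4)
  set.seed(6)
  A <- matrix(rnorm(20), 4, 5); B <- matrix(rnorm(20), 4, 5)
  expect_equal(mseLoss(A, B), sum((A - B)^2) / 20, tolerance = 1e-12)
  expect_error(mseLoss(A, t(B)), "shape")
  # finite-difference check of the gradient used for pretraining
  Z <- matrix(rnorm(6), 2, 3); X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(8), 4, 2)
  m <- linearNeuronModel(weights = Z)
  G <- decembr:::mseGradWeights(m, X, Y)
  h <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(1, 2))) {
    Zp <- Z; Zp[idx[1], idx[2]] <- Zp[idx[1], idx[2]] + h
    Zm <- Z; Zm[idx[1], idx[2]] <- Zm[idx[1], idx[2]] - h
    num <- (mseLoss(linearPredict(linearNeuronModel(weights = Zp), X), Y) -
            mseLoss(linearPredict(linearNeuronModel(weights = Zm), X), Y)) / (2 * h)
    expect_equal(G[idx[1], idx[2]], num, tolerance = 1e-5)
  }
})

test_that("Poisson loss uses the 1/N normalization and is minimized at the observation", {
  pred <- matrix(1, 3, 2); obs <- matrix(0, 3, 2)
  expect_equal(poissonLoss(pred, obs), sum(pred) / 2)
  expect_equal(poissonLoss(matrix(1, 4, 5), matrix(1, 4, 5)), 4)
  # hand formula on a 2 x 2 instance: divide by N, not by N * L
  p <- rbind(c(1.5, 2), c(0.5, 3)); r <- rbind(c(1, 2), c(0, 4))
  expect_equal(poissonLoss(p, r), sum(p - r * log(p)) / 2, tolerance = 1e-12)
  expect_error(poissonLoss(matrix(0, 1, 1), matrix(1, 1, 1)), "positive")
  # loss in a single rate is minimized where the rate equals the response
  f <- function(x) poissonLoss(matrix(x), matrix(2.5))
  expect_lt(f(2.5), f(2.0))
  expect_lt(f(2.5), f(3.0))
  expect_equal(optimize(f, c(0.1, 10))$minimum, 2.5, tolerance = 1e-4)
})

test_that("core forward produces the configured feature geometry deterministically", {
  m <- coreReadoutModel(nNeurons = 3, featureChannels = 4, hiddenChannels = 2,
                        kernelSize = 3, seed = 5)
  S <- array(rnorm(2 * 10 * 12), c(2, 10, 12, 1))
  F1 <- coreForward(m@coreParams, S)
  expect_equal(dim(F1), c(2L, 6L, 8L, 4L))
  expect_identical(F1, coreForward(m@coreParams, S))
  m2 <- coreReadoutModel(nNeurons = 3, featureChannels = 4, hiddenChannels = 2,
                         kernelSize = 3, seed = 5)
  expect_identical(m2@coreParams, m@coreParams)
  # zero input through a bias-free core gives zero pre-nonlinearity maps
  cp <- m@coreParams
  cp$b1 <- cp$b1 * 0; cp$b2 <- cp$b2 * 0
  Fz <- coreForward(cp, array(0, c(1, 8, 8, 1)))
  softplusOfZero <- log(2)
  expect_equal(max(abs(Fz - coreForward(cp, array(0, c(1, 8, 8, 1))))), 0)
  expect_equal(dim(Fz), c(1L, 4L, 4L, 4L))
  # with zero input, conv1 output is exactly 0 pre-nonlinearity
  expect_equal(as.numeric(decembr:::conv2d(array(0, c(1, 8, 8, 1)),
                                           cp$W1, cp$b1)),
               rep(0, 36 * 2))
})

test_that("readout interpolation matches the 4-corner oracle and grid identities", {
  set.seed(8)
  fm <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  w <- rnorm(3)
  # exact grid node (row 2, col 3): normalized coords
  pos <- c((3 - 1) / (6 - 1) * 2 - 1, (2 - 1) / (5 - 1) * 2 - 1)
  r <- readoutPredict(fm, pos, w)
  expect_equal(r, decembr:::softplus(sum(fm[2, 3, ] * w)) + 1e-6,
               tolerance = 1e-12)
  # midpoint of two nodes along x: average of the node feature vectors
  posMid <- c((2.5 - 1) / 5 * 2 - 1, (2 - 1) / 4 * 2 - 1)
  rMid <- readoutPredict(fm, posMid, w)
  phi <- (fm[2, 2, ] + fm[2, 3, ]) / 2
  expect_equal(rMid, decembr:::softplus(sum(phi * w)) + 1e-6, tolerance = 1e-12)
  # random positions against the oracle
  for (rep in 1:10) {
    p <- runif(2, -1, 1)
    expect_equal(readoutPredict(fm, p, w),
                 decembr:::softplus(sum(oracleBilinear(fm, p) * w)) + 1e-6,
                 tolerance = 1e-12)
  }
  # outside positions are clipped (with a message), equal to the edge value
  expect_message(rOut <- readoutPredict(fm, c(1.4, 0), w), "clipped")
  expect_equal(rOut, readoutPredict(fm, c(1, 0), w))
})

test_that("bilinear readout equals a full spatial mask that is a bilinear delta", {
  set.seed(9)
  fm <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  w <- rnorm(2)
  p <- c(0.3, -0.6)
  # build the full H x W mask with bilinear weights at the 4 corners
  H <- 3; W <- 3
  gx <- (p[1] + 1) / 2 * (W - 1); gy <- (p[2] + 1) / 2 * (H - 1)
  x0 <- floor(gx); y0 <- floor(gy); ax <- gx - x0; ay <- gy - y0
  M <- matrix(0, H, W)
  M[y0 + 1, x0 + 1] <- (1 - ax) * (1 - ay)
  M[y0 + 1, x0 + 2] <- ax * (1 - ay)
  M[y0 + 2, x0 + 1] <- (1 - ax) * ay
  M[y0 + 2, x0 + 2] <- ax * ay
  phiMask <- vapply(1:2, function(k) sum(M * fm[, , k]), numeric(1))
  expect_equal(readoutPredict(fm, p, w),
               decembr:::softplus(sum(phiMask * w)) + 1e-6, tolerance = 1e-12)
})

test_that("core-readout backprop matches finite differences on every parameter", {
  set.seed(10)
  m <- coreReadoutModel(nNeurons = 3, featureChannels = 2, hiddenChannels = 2,
                        kernelSize = 3, seed = 11)
  S <- array(rnorm(2 * 8 * 8), c(2, 8, 8, 1))
  obs <- matrix(rpois(6, 2), 2, 3)
  l2 <- 1e-3
  fwd <- decembr:::coreReadoutForward(m, S)
  gr <- decembr:::coreReadoutBackward(m, S, obs, fwd, l2 = l2)
  loss <- function(mm) decembr:::coreReadoutLoss(mm, S, obs, l2 = l2)
  h <- 1e-6
  checkGrad <- function(analytic, get, set) {
    a <- as.array(analytic)
    idx <- arrayInd(seq_along(a), dim(a))
    for (r in sample(nrow(idx), min(6, nrow(idx)))) {
      i <- idx[r, , drop = FALSE]
      num <- (loss(set(m, i, h)) - loss(set(m, i, -h))) / (2 * h)
      expect_equal(unname(a[i]), num, tolerance = 1e-4)
    }
  }
  setCore <- function(field) function(mod, i, d) {
    mod@coreParams[[field]][i] <- mod@coreParams[[field]][i] + d; mod
  }
  checkGrad(gr$W1, NULL, setCore("W1"))
  checkGrad(gr$W2, NULL, setCore("W2"))
  checkGrad(gr$b1, NULL, setCore("b1"))
  checkGrad(gr$b2, NULL, setCore("b2"))
  checkGrad(gr$weights, NULL, function(mod, i, d) {
    mod@weights[i] <- mod@weights[i] + d; mod })
  checkGrad(gr$positions, NULL, function(mod, i, d) {
    mod@positions[i] <- mod@positions[i] + d; mod })
})

test_that("predicted rates are strictly positive and positions stay in bounds", {
  m <- coreReadoutModel(nNeurons = 5, featureChannels = 3, hiddenChannels = 2,
                        kernelSize = 3, seed = 2)
  S <- array(rnorm(3 * 9 * 9, sd = 3), c(3, 9, 9, 1))
  rates <- predictResponses(m, S)
  expect_true(all(rates > 0))
  expect_equal(dim(rates), c(3L, 5L))
  expect_true(all(abs(m@positions) <= 1))
})
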