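#' Construct a miniature core-readout model
#'
#' Two valid-mode convolution layers (kernel 5, `hiddenChannels` then
#' `featureChannels` output channels) with a softplus hidden nonlinearity
#' form the shared core; each neuron owns a readout position in
#' `[-1, 1]^2` and a `featureChannels`-dimensional weight vector. Kernels
#' and readout weights are initialized as small Gaussian noise, positions
#' uniformly in the central 80% of the canvas.
#'
#' @param nNeurons number of neurons N.
#' @param inputChannels stimulus channels C (1 for grayscale).
#' @param hiddenChannels hidden feature channels of the first layer.
#' @param featureChannels embedding dimension K of the output feature map.
#' @param kernelSize convolution kernel side length.
#' @param seed seed for initialization.
#' @return a [CoreReadoutModel-class].
#' @export
coreReadoutModel <- function(nNeurons, inputChannels = 1L,
                             hiddenChannels = 9L, featureChannels = 8L,
                             kernelSize = 5L, seed = 1L) {
  withStream(seed, "init", {
    k <- kernelSize
    coreParams <- list(
      W1 = array(stats::rnorm(k * k * inputChannels * hiddenChannels,
                              sd = 0.3 / k), c(k, k, inputChannels, hiddenChannels)),
      b1 = stats::rnorm(hiddenChannels, sd = 0.01),
      W2 = array(stats::rnorm(k * k * hiddenChannels * featureChannels,
                              sd = 0.3 / k), c(k, k, hiddenChannels, featureChannels)),
      b2 = stats::rnorm(featureChannels, sd = 0.01)
    )
    positions <- matrix(stats::runif(nNeurons * 2, -0.8, 0.8), nNeurons, 2L)
    weights <- matrix(stats::rnorm(nNeurons * featureChannels, sd = 0.1),
                      nNeurons, featureChannels)
    new("CoreReadoutModel", coreParams = coreParams, positions = positions,
        weights = weights)
  })
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplusGrad <- function(x) stats::plogis(x)

# rates must stay strictly positive for the Poisson likelihood
RATE_EPS <- 1e-6

# valid-mode 2-d convolution of X [B, H, W, Cin] with kernels W
# [k, k, Cin, Cout] plus channel bias b; returns [B, Ho, Wo, Cout]
conv2d <- function(X, W, b) {
  dx <- dim(X); k1 <- dim(W)[1L]; k2 <- dim(W)[2L]
  Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  stopifnot(dx[4L] == Cin)
  B <- dx[1L]; Ho <- dx[2L] - k1 + 1L; Wo <- dx[3L] - k2 + 1L
  if (Ho < 1L || Wo < 1L) stop("stimulus smaller than kernel", call. = FALSE)
  out <- matrix(0, B * Ho * Wo, Cout)
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      Xs <- X[, i:(i + Ho - 1L), j:(j + Wo - 1L), , drop = FALSE]
      dim(Xs) <- c(B * Ho * Wo, Cin)
      out <- out + Xs %*% matrix(W[i, j, , ], Cin, Cout)
    }
  }
  out <- out + rep(b, each = B * Ho * Wo)
  array(out, c(B, Ho, Wo, Cout))
}

# gradients of conv2d w.r.t. X, W and b given upstream gradient dOut
conv2dBackward <- function(X, W, dOut) {
  dx <- dim(X); k1 <- dim(W)[1L]; k2 <- dim(W)[2L]
  Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  B <- dx[1L]; Ho <- dim(dOut)[2L]; Wo <- dim(dOut)[3L]
  dOutM <- dOut; dim(dOutM) <- c(B * Ho * Wo, Cout)
  dW <- array(0, dim(W)); dX <- array(0, dx)
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      Xs <- X[, i:(i + Ho - 1L), j:(j + Wo - 1L), , drop = FALSE]
      dim(Xs) <- c(B * Ho * Wo, Cin)
      dW[i, j, , ] <- crossprod(Xs, dOutM)
      dXs <- dOutM %*% t(matrix(W[i, j, , ], Cin, Cout))
      dim(dXs) <- c(B, Ho, Wo, Cin)
      dX[, i:(i + Ho - 1L), j:(j + Wo - 1L), ] <-
        dX[, i:(i + Ho - 1L), j:(j + Wo - 1L), , drop = FALSE] + dXs
    }
  }
  list(dX = dX, dW = dW, db = colSums(dOutM))
}

#' Forward pass of the convolutional core
#'
#' Applies the two convolution layers (softplus after the first) to a
#' batch of stimuli and returns the shared feature space.
#'
#' @param coreParams named list `W1`, `b1`, `W2`, `b2` (see
#'   [coreReadoutModel()]).
#' @param stimuli B x H' x W' x C array.
#' @return B x H x W x K feature-map array.
#' @export
coreForward <- function(coreParams, stimuli) {
  if (length(dim(stimuli)) != 4L) {
    stop("stimuli must be a B x H x W x C array", call. = FALSE)
  }
  A1 <- softplus(conv2d(stimuli, coreParams$W1, coreParams$b1))
  conv2d(A1, coreParams$W2, coreParams$b2)
}

# bilinear interpolation bookkeeping for one position on an H x W grid:
# 1-based corner indices and corner weights; gx along width, gy along height
bilinearCoeffs <- function(position, H, W) {
  pos <- pmin(1, pmax(-1, position))
  if (any(pos != position)) {
    message("readout position outside [-1, 1]^2 clipped")
  }
  gx <- (pos[1L] + 1) / 2 * (W - 1)
  gy <- (pos[2L] + 1) / 2 * (H - 1)
  x0 <- min(max(floor(gx), 0), max(W - 2, 0)); ax <- gx - x0
  y0 <- min(max(floor(gy), 0), max(H - 2, 0)); ay <- gy - y0
  list(x0 = x0 + 1L, x1 = min(x0 + 2L, W), y0 = y0 + 1L, y1 = min(y0 + 2L, H),
       ax = ax, ay = ay,
       w00 = (1 - ax) * (1 - ay), w01 = ax * (1 - ay),
       w10 = (1 - ax) * ay, w11 = ax * ay)
}

# interpolated feature vectors for all B trials at one position: B x K
gatherFeatures <- function(F, coef) {
  coef$w00 * F[, coef$y0, coef$x0, , drop = TRUE] +
    coef$w01 * F[, coef$y0, coef$x1, , drop = TRUE] +
    coef$w10 * F[, coef$y1, coef$x0, , drop = TRUE] +
    coef$w11 * F[, coef$y1, coef$x1, , drop = TRUE]
}

#' Gaussian-readout prediction at one position
#'
#' Bilinearly interpolates a feature map at a readout position (normalized
#' coordinates, `x` along width and `y` along height), takes the inner
#' product with the neuron's weight vector and maps it through a shifted
#' softplus to a strictly positive firing rate. Positions outside
#' `[-1, 1]^2` are clipped with a message.
#'
#' @param featureMap H x W x K array (one stimulus' core output).
#' @param position length-2 vector `(x, y)` in `[-1, 1]^2`.
#' @param weight K-vector of readout weights.
#' @return positive scalar predicted rate.
#' @export
readoutPredict <- function(featureMap, position, weight) {
  d <- dim(featureMap)
  stopifnot(length(d) == 3L, length(position) == 2L, length(weight) == d[3L])
  coef <- bilinearCoeffs(position, d[1L], d[2L])
  F1 <- array(featureMap, c(1L, d))
  phi <- drop(gatherFeatures(F1, coef))
  softplus(sum(phi * weight)) + RATE_EPS
}

# full forward pass with cached intermediates (training use)
coreReadoutForward <- function(model, stimuli) {
  cp <- model@coreParams
  Z1 <- conv2d(stimuli, cp$W1, cp$b1)
  A1 <- softplus(Z1)
  F <- conv2d(A1, cp$W2, cp$b2)
  dF <- dim(F)
  N <- nrow(model@weights)
  B <- dF[1L]
  pre <- matrix(0, B, N)
  coefs <- vector("list", N)
  phis <- vector("list", N)
  for (i in seq_len(N)) {
    coefs[[i]] <- bilinearCoeffs(model@positions[i, ], dF[2L], dF[3L])
    phis[[i]] <- gatherFeatures(F, coefs[[i]])
    pre[, i] <- phis[[i]] %*% model@weights[i, ]
  }
  list(Z1 = Z1, A1 = A1, F = F, pre = pre,
       rates = softplus(pre) + RATE_EPS, coefs = coefs, phis = phis)
}

#' @rdname readoutPredict
#' @param model a [CoreReadoutModel-class].
#' @param stimuli B x H' x W' x C stimulus array.
#' @export
setMethod("predictResponses", "CoreReadoutModel", function(model, stimuli) {
  coreReadoutForward(model, stimuli)$rates
})

# backward pass: gradients of (poissonLoss + l2 * ||Z||^2) w.r.t. all
# trainable parameters, given observed responses for the batch
coreReadoutBackward <- function(model, stimuli, observed, fwd, l2 = 0) {
  N <- nrow(model@weights)
  dF <- dim(fwd$F)
  B <- dF[1L]
  dRates <- (1 - observed / fwd$rates) / N        # d poissonLoss / d rate
  dPre <- dRates * softplusGrad(fwd$pre)
  dFeat <- array(0, dF)
  dWts <- matrix(0, N, ncol(model@weights))
  dPos <- matrix(0, N, 2L)
  H <- dF[2L]; W <- dF[3L]
  for (i in seq_len(N)) {
    co <- fwd$coefs[[i]]
    w <- model@weights[i, ]
    dWts[i, ] <- crossprod(fwd$phis[[i]], dPre[, i])
    dPhi <- outer(dPre[, i], w)                   # B x K
    dFeat[, co$y0, co$x0, ] <- dFeat[, co$y0, co$x0, , drop = TRUE] + co$w00 * dPhi
    dFeat[, co$y0, co$x1, ] <- dFeat[, co$y0, co$x1, , drop = TRUE] + co$w01 * dPhi
    dFeat[, co$y1, co$x0, ] <- dFeat[, co$y1, co$x0, , drop = TRUE] + co$w10 * dPhi
    dFeat[, co$y1, co$x1, ] <- dFeat[, co$y1, co$x1, , drop = TRUE] + co$w11 * dPhi
    # position gradient through the bilinear weights
    F00 <- fwd$F[, co$y0, co$x0, , drop = TRUE]
    F01 <- fwd$F[, co$y0, co$x1, , drop = TRUE]
    F10 <- fwd$F[, co$y1, co$x0, , drop = TRUE]
    F11 <- fwd$F[, co$y1, co$x1, , drop = TRUE]
    dPhidAx <- (1 - co$ay) * (F01 - F00) + co$ay * (F11 - F10)
    dPhidAy <- (1 - co$ax) * (F10 - F00) + co$ax * (F11 - F01)
    dPos[i, 1L] <- sum(dPhi * dPhidAx) * (W - 1) / 2
    dPos[i, 2L] <- sum(dPhi * dPhidAy) * (H - 1) / 2
  }
  cp <- model@coreParams
  b2g <- conv2dBackward(fwd$A1, cp$W2, dFeat)
  dA1 <- b2g$dX * softplusGrad(fwd$Z1)
  b1g <- conv2dBackward(stimuli, cp$W1, dA1)
  list(W1 = b1g$dW, b1 = b1g$db, W2 = b2g$dW, b2 = b2g$db,
       positions = dPos, weights = dWts + 2 * l2 * model@weights)
}

# model loss of a core-readout model on a batch: Poisson + L2 on readout
coreReadoutLoss <- function(model, stimuli, observed, l2 = 0) {
  rates <- coreReadoutForward(model, stimuli)$rates
  poissonLoss(rates, observed) + l2 * sum(model@weights^2)
}
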