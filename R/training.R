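# ---- parameter plumbing ------------------------------------------------

getParams <- function(model) {
  if (is(model, "LinearNeuronModel")) {
    list(weights = model@weights)
  } else if (is(model, "CoreReadoutModel")) {
    c(model@coreParams, list(positions = model@positions,
                             weights = model@weights))
  } else stop("unsupported model class", call. = FALSE)
}

setParams <- function(model, params) {
  if (is(model, "LinearNeuronModel")) {
    model@weights <- params$weights
  } else {
    model@coreParams <- params[c("W1", "b1", "W2", "b2")]
    model@positions <- pmin(pmax(params$positions, -1), 1)
    model@weights <- params$weights
  }
  model
}

zeroLike <- function(params) lapply(params, function(p) array(0, dim(as.array(p))))

# model loss and its gradients on one batch
modelLossGrad <- function(model, stim, resp, l2 = 0) {
  if (is(model, "LinearNeuronModel")) {
    pred <- linearPredict(model, stim)
    list(loss = mseLoss(pred, resp),
         grads = list(weights = (2 / length(pred)) *
                        crossprod(pred - resp, stim)))
  } else {
    fwd <- coreReadoutForward(model, stim)
    list(loss = poissonLoss(fwd$rates, resp) + l2 * sum(model@weights^2),
         grads = coreReadoutBackward(model, stim, resp, fwd, l2 = l2))
  }
}

modelLossOnly <- function(model, stim, resp, l2 = 0) {
  if (is(model, "LinearNeuronModel")) {
    mseLoss(linearPredict(model, stim), resp)
  } else {
    coreReadoutLoss(model, stim, resp, l2 = l2)
  }
}

sliceStimuli <- function(stimuli, idx) {
  if (length(dim(stimuli)) == 4L) stimuli[idx, , , , drop = FALSE]
  else stimuli[idx, , drop = FALSE]
}

# last 10% of trials are held out for validation monitoring
splitTrials <- function(B, valFraction = 0.1) {
  nVal <- max(1L, floor(B * valFraction))
  list(train = seq_len(B - nVal), val = seq.int(B - nVal + 1L, B))
}

# gradient of the KL clustering loss w.r.t. the embedding matrix, with the
# target P held constant:
#   dL/dz_i = sum_j (p_ij - q_ij) u_ij Sigma_j^{-1} (z_i - mu_j)
clusterGradEmbeddings <- function(Z, state, Q, U, P) {
  G <- matrix(0, nrow(Z), ncol(Z))
  for (j in seq_len(nrow(state@centers))) {
    coefs <- (P[, j] - Q[, j]) * U[, j]
    G <- G + coefs * sweep(sweep(Z, 2L, state@centers[j, ]), 2L,
                           state@scaleDiags[j, ], "/")
  }
  G
}

# ---- fixed-unit-scale (vanilla deep-embedding-clustering) machinery ----

# soft assignments under a unit-scale t kernel with nu = 1 (Cauchy):
# q_ij propto (1 + ||z_i - mu_j||^2)^(-1)
decSoftAssign <- function(Z, centers) {
  nu <- 1
  J <- nrow(centers)
  logf <- delta <- matrix(0, nrow(Z), J)
  for (j in seq_len(J)) {
    d <- colSums((t(Z) - centers[j, ])^2)
    delta[, j] <- d
    logf[, j] <- -((nu + 1) / 2) * log1p(d / nu)
  }
  list(Q = exp(logf - rowLogSumExp(logf)), W = (nu + 1) / (nu + delta))
}

decGradients <- function(Z, centers, Q, W, P) {
  J <- nrow(centers)
  GZ <- matrix(0, nrow(Z), ncol(Z))
  GC <- matrix(0, J, ncol(Z))
  for (j in seq_len(J)) {
    coefs <- (P[, j] - Q[, j]) * W[, j]
    dev <- sweep(Z, 2L, centers[j, ])
    GZ <- GZ + coefs * dev
    GC[j, ] <- -colSums(coefs * dev)
  }
  list(Z = GZ, centers = GC)
}

# ---- the training engine ----------------------------------------------

# One engine drives pretraining, the EM-clustered joint loop and the
# fixed-unit-scale ablation. Epoch-wise batch shuffling draws from the
# "batch-<globalEpoch>" stream of the master seed, so a run that
# continues at epoch offset m is bit-identical to the tail of a longer
# run. Learning rate halves on a validation-loss plateau (min 1e-5);
# with patience > 0 training stops early after `patience` epochs without
# improvement.
trainEngine <- function(model, dataset, config, nEpochs, epochOffset = 0L,
                        clustering = c("none", "em", "dec-mean", "dec-grad"),
                        beta = config@beta, modelLossWeight = 1,
                        state = NULL, trace = FALSE) {
  clustering <- match.arg(clustering)
  stim <- dataset@stimuli
  resp <- dataset@responses
  B <- dim(stim)[1L]
  sp <- splitTrials(B)
  l2 <- if (is(model, "CoreReadoutModel")) config@l2Readout else 0
  params <- getParams(model)
  decCenters <- NULL
  if (clustering %in% c("dec-mean", "dec-grad")) {
    decCenters <- state                 # plain matrix for the ablation
    state <- NULL
    if (clustering == "dec-grad") params$decCenters <- decCenters
  }
  # the gradient-updated ablation replicates the original deep-embedding-
  # clustering setup, whose optimizer is SGD with momentum; its dynamics
  # depend on the unnormalized gradient-magnitude ratio between centers
  # and single embeddings, which adaptive-moment normalization would erase
  useSGD <- clustering == "dec-grad"
  opt <- if (useSGD) sgdInit(params, lr = config@learningRate)
         else adamInit(params, lr = config@learningRate)
  stepFun <- if (useSGD) sgdStep else adamStep
  logRows <- list()
  centerTrace <- list()
  bestVal <- Inf
  stall <- 0L
  clusterLossVal <- NA_real_
  for (e in seq_len(nEpochs)) {
    idx <- withStream(config@seed, paste0("batch-", epochOffset + e),
                      sample(sp$train))
    nb <- max(1L, length(idx) %/% config@batchSize)
    batchStarts <- floor(seq(0L, length(idx), length.out = nb + 1L))
    epochModelLoss <- 0
    for (b in seq_len(nb)) {
      bi <- idx[(batchStarts[b] + 1L):batchStarts[b + 1L]]
      grads <- zeroLike(params)
      # E/M over all N embeddings, then one gradient step on
      # L = modelLossWeight * L_model(batch) + beta * L_cluster(full)
      if (clustering == "em") {
        Z <- params$weights
        es <- eStep(Z, state)
        state <- refreshEmptyClusters(Z, es$Q, state)
        state <- mStep(Z, es$Q, es$U, state)
        es <- eStep(Z, state)
        td <- targetDistribution(es$Q)
        clusterLossVal <- clusteringLoss(es$Q, td$P)
        if (beta > 0) {
          grads$weights <- grads$weights + beta *
            clusterGradEmbeddings(Z, state, es$Q, es$U, td$P)
        }
      } else if (clustering == "dec-mean") {
        # unit-scale position update without scale adaptation: each
        # center becomes the q-weighted mean of all embeddings, then one
        # gradient step moves the embeddings under the KL loss
        Z <- params$weights
        if (beta > 0) {
          sa <- decSoftAssign(Z, decCenters)
          decCenters <- crossprod(sa$Q, Z) / colSums(sa$Q)
        }
        sa <- decSoftAssign(Z, decCenters)
        td <- targetDistribution(sa$Q)
        clusterLossVal <- clusteringLoss(sa$Q, td$P)
        if (beta > 0) {
          dg <- decGradients(Z, decCenters, sa$Q, sa$W, td$P)
          grads$weights <- grads$weights + beta * dg$Z
        }
      } else if (clustering == "dec-grad") {
        Z <- params$weights
        sa <- decSoftAssign(Z, params$decCenters)
        td <- targetDistribution(sa$Q)
        clusterLossVal <- clusteringLoss(sa$Q, td$P)
        if (beta > 0) {
          dg <- decGradients(Z, params$decCenters, sa$Q, sa$W, td$P)
          grads$weights <- grads$weights + beta * dg$Z
          grads$decCenters <- grads$decCenters + beta * dg$centers
        }
      }
      if (modelLossWeight > 0) {
        mg <- modelLossGrad(setParams(model, params),
                            sliceStimuli(stim, bi),
                            resp[bi, , drop = FALSE], l2 = l2)
        if (!is.finite(mg$loss)) {
          stop(sprintf(
            "divergence: non-finite model loss at epoch %d (lr = %g)",
            epochOffset + e, opt$lr), call. = FALSE)
        }
        epochModelLoss <- epochModelLoss + mg$loss / nb
        for (nm in names(mg$grads)) {
          grads[[nm]] <- grads[[nm]] + modelLossWeight * mg$grads[[nm]]
        }
      }
      params <- stepFun(opt, params, grads)
      if (clustering == "dec-grad") {
        model <- setParams(model, params[setdiff(names(params), "decCenters")])
      } else {
        model <- setParams(model, params)
      }
      params[names(getParams(model))] <- getParams(model)  # position clip
    }
    # epoch bookkeeping on the validation split
    valModelLoss <- modelLossOnly(model, sliceStimuli(stim, sp$val),
                                  resp[sp$val, , drop = FALSE], l2 = l2)
    valMetric <- if (is(model, "CoreReadoutModel")) {
      suppressWarnings(meanNeuronCorrelation(
        predictResponses(model, sliceStimuli(stim, sp$val)),
        resp[sp$val, , drop = FALSE]))
    } else valModelLoss
    schedLoss <- modelLossWeight * valModelLoss +
      (if (is.finite(clusterLossVal)) beta * clusterLossVal else 0)
    totalLoss <- modelLossWeight * epochModelLoss +
      (if (is.na(clusterLossVal)) 0 else beta * clusterLossVal)
    if (!is.finite(totalLoss)) {
      stop(sprintf("divergence: non-finite total loss at epoch %d (lr = %g)",
                   epochOffset + e, opt$lr), call. = FALSE)
    }
    logRows[[e]] <- data.frame(
      epoch = epochOffset + e,
      phase = if (clustering == "none") "model" else clustering,
      modelLoss = epochModelLoss, clusterLoss = clusterLossVal,
      totalLoss = totalLoss, valMetric = valMetric)
    if (trace) {
      cc <- if (clustering == "em") state@centers
            else if (clustering == "dec-grad") params$decCenters
            else if (clustering == "dec-mean") decCenters else NULL
      if (!is.null(cc)) centerTrace[[e]] <- cc
    }
    if (!is.finite(bestVal) ||
        schedLoss < bestVal - 1e-6 * max(1, abs(bestVal))) {
      bestVal <- schedLoss
      stall <- 0L
    } else if (config@patience > 0L) {
      stall <- stall + 1L
      if (stall %% max(1L, config@patience %/% 2L) == 0L) {
        opt$lr <- max(opt$lr * 0.5, 1e-5)
      }
      if (stall >= config@patience) break
    }
  }
  list(model = model, state = state,
       decCenters = if (clustering == "dec-grad") params$decCenters
                    else if (clustering == "dec-mean") decCenters else NULL,
       log = do.call(rbind, logRows), centerTrace = centerTrace)
}

#' Pretrain a predictive model on its model loss alone
#'
#' Runs `epochs` epochs of Adam on the predictive loss only: mean squared
#' error for a [LinearNeuronModel-class], Poisson loss plus an L2 penalty
#' on readout weights for a [CoreReadoutModel-class]. Fully reproducible
#' from `config@seed`.
#'
#' @param model the model to train.
#' @param dataset a [StimulusResponseDataset-class].
#' @param config a [TrainConfig-class]; `config@pretrainEpochs` epochs are
#'   run unless `epochs` overrides it.
#' @param epochs optional epoch-count override.
#' @param epochOffset global epoch index offset (continuing a run at
#'   offset m reproduces the tail of a longer run bit-identically).
#' @return the trained model.
#' @export
pretrain <- function(model, dataset, config, epochs = NULL, epochOffset = 0L) {
  epochs <- if (is.null(epochs)) config@pretrainEpochs else as.integer(epochs)
  if (epochs == 0L) return(model)
  trainEngine(model, dataset, config, nEpochs = epochs,
              epochOffset = epochOffset, clustering = "none")$model
}

#' Joint training with the EM-refined clustering loss
#'
#' The main fitting loop: after initializing a t-mixture on the model's
#' current embeddings with seeded k-means, every minibatch performs an
#' E-step and an M-step over all N embeddings followed by one Adam step on
#' \deqn{L = w_{model}\,L_{model}(batch) + \beta\,KL(P\Vert Q)}
#' where the target P is recomputed from Q each batch and treated as a
#' constant, and cluster parameters receive no gradients (EM only).
#'
#' @param model a pretrained model (call [pretrain()] first, or pass
#'   `pretrainEpochs = 0` deliberately).
#' @param dataset a [StimulusResponseDataset-class].
#' @param config a [TrainConfig-class]; the clustering phase runs
#'   `totalEpochs - pretrainEpochs` epochs at weight `config@beta`.
#' @param modelLossWeight weight of the predictive loss during the
#'   clustering phase; the linear-toy protocol sets it to 0 (clustering
#'   loss only), the general runner keeps 1.
#' @param trace record the center trajectory per epoch (for figures).
#' @return a [TrainResult-class].
#' @export
decemberFit <- function(model, dataset, config, modelLossWeight = 1,
                        trace = FALSE) {
  Z <- embeddings(model)
  if (nrow(Z) < config@numClusters) {
    stop("fewer embeddings than clusters", call. = FALSE)
  }
  state <- initClusters(Z, config@numClusters, seed = config@seed,
                        dof = config@dof, clampFloor = config@clampFloor)
  nEpochs <- config@totalEpochs - config@pretrainEpochs
  out <- trainEngine(model, dataset, config, nEpochs = nEpochs,
                     epochOffset = config@pretrainEpochs,
                     clustering = "em", beta = config@beta,
                     modelLossWeight = modelLossWeight, state = state,
                     trace = trace)
  es <- eStep(embeddings(out$model), out$state)
  res <- new("TrainResult", model = out$model, state = out$state,
             log = out$log, mapLabels = mapAssign(es$Q), seed = config@seed)
  attr(res, "centerTrace") <- out$centerTrace
  res
}

#' Fixed-unit-scale ablation (vanilla deep embedding clustering)
#'
#' Same loop as [decemberFit()] but with soft assignments from a
#' unit-scale t kernel with one degree of freedom and no scale
#' adaptation. This is the configuration whose cluster centers collapse
#' to a single point on data whose cluster scale is far from 1 — kept
#' only to reproduce that failure mode.
#'
#' With the default `centerUpdate = "soft-mean"`, each batch moves every
#' center to the q-weighted mean of all embeddings (the position update
#' with scales frozen at the identity): on data much tighter than the
#' unit kernel the soft assignments mix the groups and the centers
#' contract geometrically to the global weighted mean within a few
#' iterations, while the embeddings barely move before the uniform-Q
#' degenerate optimum (KL = 0) freezes all gradients.
#' `centerUpdate = "gradient"` instead updates the centers by SGD with
#' momentum 0.9 on the KL loss (the original deep-embedding-clustering
#' optimizer); on this toy geometry that variant separates rather than
#' collapses, because the frequency-normalized target pushes each center
#' away from the opposite cluster.
#'
#' @inheritParams decemberFit
#' @param centerUpdate `"soft-mean"` (default) or `"gradient"`; see
#'   Details.
#' @return a [TrainResult-class]; `mixtureState(result)` is a plain list
#'   with the final `centers` matrix.
#' @export
decUnitScaleFit <- function(model, dataset, config, modelLossWeight = 1,
                            trace = FALSE,
                            centerUpdate = c("soft-mean", "gradient")) {
  centerUpdate <- match.arg(centerUpdate)
  Z <- embeddings(model)
  if (nrow(Z) < config@numClusters) {
    stop("fewer embeddings than clusters", call. = FALSE)
  }
  km <- withStream(config@seed, "kmeans",
                   stats::kmeans(Z, config@numClusters, nstart = 10L,
                                 iter.max = 100L))
  nEpochs <- config@totalEpochs - config@pretrainEpochs
  out <- trainEngine(model, dataset, config, nEpochs = nEpochs,
                     epochOffset = config@pretrainEpochs,
                     clustering = if (centerUpdate == "soft-mean") "dec-mean"
                                  else "dec-grad",
                     beta = config@beta,
                     modelLossWeight = modelLossWeight,
                     state = unname(km$centers), trace = trace)
  sa <- decSoftAssign(embeddings(out$model), out$decCenters)
  res <- new("TrainResult", model = out$model,
             state = list(centers = out$decCenters), log = out$log,
             mapLabels = mapAssign(sa$Q), seed = config@seed)
  attr(res, "centerTrace") <- out$centerTrace
  res
}

#' Order-of-magnitude heuristic for the clustering weight
#'
#' Evaluates the model loss and the clustering loss once at
#' clustering-start (pretrained model, k-means-initialized clusters) and
#' returns \eqn{\beta = 10^{\mathrm{round}(\log_{10}(L_{model}/L_{cluster}))}},
#' i.e. the power of ten that puts \eqn{\beta L_{cluster}} on the same
#' order of magnitude as the model loss.
#'
#' @inheritParams decemberFit
#' @return a positive scalar; if the clustering loss is exactly 0 at
#'   start, returns `config@beta` with a warning.
#' @export
betaHeuristic <- function(model, dataset, config) {
  sp <- splitTrials(dim(dataset@stimuli)[1L])
  l2 <- if (is(model, "CoreReadoutModel")) config@l2Readout else 0
  Lm <- modelLossOnly(model, sliceStimuli(dataset@stimuli, sp$train),
                      dataset@responses[sp$train, , drop = FALSE], l2 = l2)
  Z <- embeddings(model)
  state <- initClusters(Z, config@numClusters, seed = config@seed,
                        dof = config@dof, clampFloor = config@clampFloor)
  es <- eStep(Z, state)
  Lc <- clusteringLoss(es$Q, targetDistribution(es$Q)$P)
  if (Lc <= 0) {  # KL is nonnegative; <= 0 means numerically zero
    warning("clustering loss is 0 at start; returning the configured beta")
    return(config@beta)
  }
  # the Poisson loss omits the constant log(r!) term and can be negative;
  # only the order of magnitude of the loss is meaningful here
  10^round(log10(abs(Lm) / Lc))
}
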