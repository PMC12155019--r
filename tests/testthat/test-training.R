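# fast shared fixtures: a miniature two-group linear population
miniSetup <- function(seed = 1, lr = 0.02) {
  ds <- genToyLinear(miniToySpec(seed = seed))
  cfg <- trainConfig(beta = 1, pretrainEpochs = 15L, totalEpochs = 30L,
                     learningRate = lr, batchSize = 64L, numClusters = 2L,
                     seed = seed, modelKind = "linear-toy", patience = 0L)
  model <- linearNeuronModel(nNeurons = ncol(responses(ds)),
                             dim = ncol(stimuli(ds)), seed = seed)
  list(ds = ds, cfg = cfg, model = model)
}

test_that("pretraining is reproducible, beats the mean predictor, and m = 0 is a no-op", {
  s <- miniSetup(seed = 2)
  expect_identical(embeddings(pretrain(s$model, s$ds, s$cfg, epochs = 0L)),
                   embeddings(s$model))
  m1 <- pretrain(s$model, s$ds, s$cfg)
  m2 <- pretrain(s$model, s$ds, s$cfg)
  expect_identical(embeddings(m1), embeddings(m2))
  val <- decembr:::splitTrials(nrow(responses(s$ds)))$val
  pred <- linearPredict(m1, stimuli(s$ds)[val, ])
  obs <- responses(s$ds)[val, ]
  expect_lt(mseLoss(pred, obs), mean(apply(obs, 2, var)))
})

test_that("with beta = 0 the joint fit reproduces continued pretraining bit-identically", {
  s <- miniSetup(seed = 3)
  pre <- pretrain(s$model, s$ds, s$cfg)
  cfg0 <- s$cfg; cfg0@beta <- 0
  res <- decemberFit(pre, s$ds, cfg0)
  cont <- pretrain(pre, s$ds, s$cfg,
                   epochs = s$cfg@totalEpochs - s$cfg@pretrainEpochs,
                   epochOffset = s$cfg@pretrainEpochs)
  expect_identical(embeddings(res), embeddings(cont))
})

test_that("the joint fit recovers the planted toy groups and sharpens clustering", {
  s <- miniSetup(seed = 4)
  pre <- pretrain(s$model, s$ds, s$cfg)
  res <- decemberFit(pre, s$ds, s$cfg, modelLossWeight = 0)
  expect_equal(as.vector(table(mapLabels(res))[order(-table(mapLabels(res)))]),
               c(80L, 20L))
  expect_equal(adjustedRandIndex(mapLabels(res), trueLabels(s$ds)), 1)
  lg <- trainLog(res)
  expect_equal(nrow(lg), 15L)
  expect_true(all(is.finite(lg$totalLoss)))
  # clustering loss decreases over the phase (5-epoch moving average)
  ma <- stats::filter(lg$clusterLoss, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(tail(ma, 1), head(ma, 1) + 1e-12)
  # determinism of the whole pipeline
  res2 <- decemberFit(pre, s$ds, s$cfg, modelLossWeight = 0)
  expect_identical(centers(mixtureState(res)), centers(mixtureState(res2)))
})

test_that("the gradient step sees the mixture state produced by that batch's M-step", {
  # one batch, one epoch: the returned state must equal the M-step of the
  # E-step on the pre-update embeddings (interleaving order E -> M -> grad)
  s <- miniSetup(seed = 5)
  pre <- pretrain(s$model, s$ds, s$cfg)
  cfg1 <- s$cfg
  cfg1@totalEpochs <- s$cfg@pretrainEpochs + 1L
  cfg1@batchSize <- 400L   # single batch per epoch
  res <- decemberFit(pre, s$ds, cfg1, modelLossWeight = 0)
  Z0 <- embeddings(pre)
  st0 <- initClusters(Z0, 2, seed = cfg1@seed, dof = cfg1@dof,
                      clampFloor = cfg1@clampFloor)
  es0 <- eStep(Z0, st0)
  stExpect <- mStep(Z0, es0$Q, es0$U, st0)
  expect_equal(centers(mixtureState(res)), centers(stExpect), tolerance = 1e-12)
  expect_equal(scaleDiags(mixtureState(res)), scaleDiags(stExpect),
               tolerance = 1e-12)
})

test_that("the unit-scale ablation collapses where the adaptive-scale fit does not", {
  s <- miniSetup(seed = 6)
  pre <- pretrain(s$model, s$ds, s$cfg)
  dec <- decUnitScaleFit(pre, s$ds, s$cfg, modelLossWeight = 0)
  dDec <- as.numeric(dist(mixtureState(dec)$centers))
  expect_lt(dDec, 1e-2)
  # adaptive-scale centers stay far from coincidence (the full-scale
  # toy contrast, separation > 1, is asserted in the acceptance suite)
  emres <- decemberFit(pre, s$ds, s$cfg, modelLossWeight = 0)
  expect_gt(as.numeric(dist(centers(mixtureState(emres)))), 100 * dDec)
  expect_gt(as.numeric(dist(centers(mixtureState(emres)))), 0.3)
})

test_that("well-separated unit-scale-appropriate clusters do not collapse", {
  blobs <- makeBlobs(n = 120, K = 2, centers = rbind(c(0, 0), c(9, 9)),
                     sd = 0.4, seed = 7)
  ds <- decembr:::stimulusResponseDataset(
    stimuli = matrix(rnorm(40), 20, 2),
    responses = matrix(rnorm(20 * 120), 20, 120),
    trueLabels = blobs$labels)
  cfg <- trainConfig(beta = 1, pretrainEpochs = 0L, totalEpochs = 10L,
                     learningRate = 0.01, batchSize = 10L, numClusters = 2L,
                     seed = 8, modelKind = "linear-toy", patience = 0L)
  m <- linearNeuronModel(weights = blobs$Z)
  res <- decUnitScaleFit(m, ds, cfg, modelLossWeight = 0)
  expect_gt(as.numeric(dist(mixtureState(res)$centers)), 5)
  expect_equal(adjustedRandIndex(mapLabels(res), blobs$labels), 1)
})

test_that("the clustering weight heuristic returns the matching power of ten", {
  # arithmetic of the heuristic, checked through a crafted configuration
  # a lightly-pretrained model keeps the soft assignments diffuse so the
  # clustering loss at start is strictly positive
  s <- miniSetup(seed = 9)
  pre <- pretrain(s$model, s$ds, s$cfg, epochs = 3L)
  beta <- betaHeuristic(pre, s$ds, s$cfg)
  sp <- decembr:::splitTrials(nrow(responses(s$ds)))
  Lm <- mseLoss(linearPredict(pre, stimuli(s$ds)[sp$train, ]),
                responses(s$ds)[sp$train, ])
  st <- initClusters(embeddings(pre), 2, seed = s$cfg@seed,
                     dof = s$cfg@dof, clampFloor = s$cfg@clampFloor)
  es <- eStep(embeddings(pre), st)
  Lc <- clusteringLoss(es$Q, targetDistribution(es$Q)$P)
  expect_equal(beta, 10^round(log10(Lm / Lc)))
  expect_equal(log10(beta) %% 1, 0)
})

test_that("a zero clustering loss at start falls back to the configured beta", {
  # two exact point masses: k-means separates them perfectly, Q is one-hot,
  # hence P = Q and the clustering loss is exactly 0
  Z <- rbind(matrix(0, 10, 2), matrix(10, 10, 2))
  ds <- decembr:::stimulusResponseDataset(
    stimuli = matrix(rnorm(8), 4, 2), responses = matrix(rnorm(80), 4, 20))
  cfg <- trainConfig(beta = 7, numClusters = 2L, seed = 1,
                     modelKind = "linear-toy")
  m <- linearNeuronModel(weights = Z)
  expect_warning(beta <- betaHeuristic(m, ds, cfg), "0 at start")
  expect_equal(beta, 7)
})

test_that("training rejects impossible setups and reports divergence", {
  s <- miniSetup(seed = 10)
  cfgBig <- s$cfg
  cfgBig@numClusters <- 1000L
  expect_error(decemberFit(s$model, s$ds, cfgBig), "fewer")
  cfgHot <- s$cfg
  cfgHot@learningRate <- 1e200
  expect_error(pretrain(s$model, s$ds, cfgHot, epochs = 5L), "divergence")
})
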