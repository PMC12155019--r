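#' Specification of the linear-neuron toy dataset
#'
#' Defaults reproduce the two-group linear-neuron benchmark exactly:
#' 8000 stimuli uniform on \eqn{(-1,1)^{30}}; 2500 neurons split 2000/500;
#' group 1 weights \eqn{1 + U(-1/300, 1/300)} per coordinate, group 2
#' weights \eqn{1.5 + U(-1/120, 1/120)}; responses \eqn{y_i = z_i^\top x}
#' noise-free. Every field can be overridden.
#'
#' @param nStimuli number of stimuli.
#' @param dim stimulus/embedding dimension K.
#' @param groupSizes integer vector of group sizes (sums to N).
#' @param groupCenters per-coordinate weight center of each group.
#' @param noiseHalfWidths half-width of the uniform weight jitter per group.
#' @param seed integer seed.
#' @return a list of class `ToySpec`.
#' @export
toySpec <- function(nStimuli = 8000L, dim = 30L,
                    groupSizes = c(2000L, 500L),
                    groupCenters = c(1.0, 1.5),
                    noiseHalfWidths = c(1 / 300, 1 / 120),
                    seed = 1L) {
  stopifnot(length(groupSizes) == length(groupCenters),
            length(groupSizes) == length(noiseHalfWidths),
            all(groupSizes >= 1), nStimuli >= 1, dim >= 1)
  structure(list(nStimuli = as.integer(nStimuli), dim = as.integer(dim),
                 groupSizes = as.integer(groupSizes),
                 groupCenters = groupCenters,
                 noiseHalfWidths = noiseHalfWidths,
                 seed = as.integer(seed)),
            class = "ToySpec")
}

#' Generate the linear-neuron toy dataset
#'
#' @param spec a [toySpec()] object.
#' @return a [StimulusResponseDataset-class] with stimuli, noise-free
#'   responses, true labels and true weights.
#' @export
#' @examples
#' ds <- genToyLinear(toySpec(nStimuli = 100, groupSizes = c(30, 10)))
#' ds
genToyLinear <- function(spec = toySpec()) {
  stopifnot(inherits(spec, "ToySpec"))
  withStream(spec$seed, "data", {
    X <- matrix(stats::runif(spec$nStimuli * spec$dim, -1, 1),
                spec$nStimuli, spec$dim)
    G <- length(spec$groupSizes)
    Z <- do.call(rbind, lapply(seq_len(G), function(g) {
      n <- spec$groupSizes[g]
      spec$groupCenters[g] +
        matrix(stats::runif(n * spec$dim, -spec$noiseHalfWidths[g],
                            spec$noiseHalfWidths[g]), n, spec$dim)
    }))
    labels <- rep(seq_len(G), spec$groupSizes)
    stimulusResponseDataset(stimuli = X, responses = X %*% t(Z),
                            trueLabels = labels, trueWeights = Z)
  })
}

#' Specification of a planted-cluster Poisson population
#'
#' A synthetic population emulating the structure the clustering loss
#' assumes: per-neuron readout weights drawn from compact planted
#' clusters, receptive-field positions uniform on the canvas, firing
#' rates produced by a fixed randomly-drawn convolutional core applied
#' to white-noise stimuli, and integer spike counts Poisson-distributed
#' around those rates. Cluster centers are drawn i.i.d.
#' \eqn{N(0, s^2 I_K)} with \eqn{s = separation \cdot spread / \sqrt 2},
#' so the typical per-coordinate center distance is `separation` within-
#' cluster standard deviations; `separation = 0` plants no structure.
#'
#' @param nNeurons number of neurons.
#' @param dim embedding dimension K (core feature channels).
#' @param nTrueClusters number of planted clusters.
#' @param separation center separation in pooled within-cluster scale units.
#' @param spread within-cluster standard deviation per coordinate.
#' @param nStimuli number of noise stimuli.
#' @param stimulusSize stimulus side length in pixels (square, grayscale).
#' @param meanRate target mean firing rate (spikes per trial).
#' @param coreGain multiplier on the generating core's kernels; larger
#'   values strengthen stimulus-driven rate modulation relative to the
#'   Poisson noise floor.
#' @param smoothStimuli smooth the white noise with two passes of a 3 x 3
#'   box filter (spatially correlated, natural-stimulus-like input that
#'   drives convolutional features much more strongly than white noise).
#' @param seed integer seed.
#' @return a list of class `PlantedPopulationSpec`.
#' @export
plantedPopulationSpec <- function(nNeurons = 200L, dim = 8L,
                                  nTrueClusters = 3L, separation = 8,
                                  spread = 0.15, nStimuli = 1500L,
                                  stimulusSize = 20L, meanRate = 5,
                                  coreGain = 4, smoothStimuli = TRUE,
                                  seed = 1L) {
  stopifnot(nNeurons >= nTrueClusters, meanRate > 0, spread > 0,
            coreGain > 0)
  structure(list(nNeurons = as.integer(nNeurons), dim = as.integer(dim),
                 nTrueClusters = as.integer(nTrueClusters),
                 separation = separation, spread = spread,
                 nStimuli = as.integer(nStimuli),
                 stimulusSize = as.integer(stimulusSize),
                 meanRate = meanRate, coreGain = coreGain,
                 smoothStimuli = isTRUE(smoothStimuli),
                 seed = as.integer(seed)),
            class = "PlantedPopulationSpec")
}

# two passes of a same-size 3x3 box filter (edge padding), then rescale
# to unit standard deviation
smoothStimulusArray <- function(S) {
  H <- dim(S)[2L]; W <- dim(S)[3L]
  for (pass in 1:2) {
    Sp <- S[, c(1L, seq_len(H), H), c(1L, seq_len(W), W), , drop = FALSE]
    acc <- array(0, dim(S))
    for (dy in 0:2) for (dx in 0:2) {
      acc <- acc + Sp[, dy + seq_len(H), dx + seq_len(W), , drop = FALSE]
    }
    S <- acc / 9
  }
  S / stats::sd(S)
}

#' Generate a planted-cluster Poisson population
#'
#' @param spec a [plantedPopulationSpec()] object.
#' @return a [StimulusResponseDataset-class]; responses are integer counts,
#'   with true labels, true weights and true positions attached. The
#'   generating core is stored in `attr(dataset, "trueCore")`.
#' @export
genPoissonPopulation <- function(spec = plantedPopulationSpec()) {
  stopifnot(inherits(spec, "PlantedPopulationSpec"))
  gen <- withStream(spec$seed, "data", {
    J <- spec$nTrueClusters
    s <- spec$separation * spec$spread / sqrt(2)
    centers <- matrix(stats::rnorm(J * spec$dim, sd = s), J, spec$dim)
    labels <- sort(rep_len(seq_len(J), spec$nNeurons))
    Z <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(spec$nNeurons * spec$dim, sd = spec$spread),
             spec$nNeurons, spec$dim)
    positions <- matrix(stats::runif(spec$nNeurons * 2, -0.8, 0.8),
                        spec$nNeurons, 2L)
    S <- array(stats::rnorm(spec$nStimuli * spec$stimulusSize^2),
               c(spec$nStimuli, spec$stimulusSize, spec$stimulusSize, 1L))
    list(centers = centers, labels = labels, Z = Z, positions = positions,
         S = S)
  })
  if (spec$smoothStimuli) gen$S <- smoothStimulusArray(gen$S)
  # a fixed, known core defines the ground-truth stimulus-response map
  trueModel <- coreReadoutModel(nNeurons = spec$nNeurons, inputChannels = 1L,
                                hiddenChannels = 9L,
                                featureChannels = spec$dim,
                                seed = deriveSeed(spec$seed, "truecore"))
  trueModel@coreParams$W1 <- trueModel@coreParams$W1 * spec$coreGain
  trueModel@coreParams$W2 <- trueModel@coreParams$W2 * spec$coreGain
  trueModel@weights <- gen$Z
  trueModel@positions <- gen$positions
  rates <- predictResponses(trueModel, gen$S)
  if (any(rates <= 0) || mean(rates) <= 0) {
    stop("rate construction produced nonpositive rates", call. = FALSE)
  }
  rates <- rates * (spec$meanRate / mean(rates))
  counts <- withStream(spec$seed, "counts", {
    matrix(stats::rpois(length(rates), rates), nrow(rates), ncol(rates))
  })
  ds <- stimulusResponseDataset(stimuli = gen$S, responses = counts,
                                trueLabels = gen$labels, trueWeights = gen$Z,
                                truePositions = gen$positions)
  attr(ds, "trueCore") <- trueModel@coreParams
  ds
}

#' Sample from a Student's t-mixture via its shape-rate form
#'
#' Components are chosen uniformly (equal mixing weights `1/J`); each draw
#' uses the Gamma-mixture-of-Gaussians representation
#' \eqn{u \sim Gamma(\nu/2, \nu/2)}, \eqn{z \sim N(\mu_j, \Sigma_j / u)}.
#'
#' @param state a [TMixtureState-class].
#' @param n number of draws.
#' @param seed integer seed.
#' @return list with `samples` (n x K matrix) and `labels` (component ids).
#' @export
#' @examples
#' st <- tMixtureState(rbind(c(0, 0), c(5, 5)), rbind(c(1, 1), c(1, 1)))
#' out <- genTMMSamples(st, 100, seed = 1)
#' table(out$labels)
genTMMSamples <- function(state, n, seed) {
  stopifnot(n >= 1)
  withStream(seed, "tmm", {
    J <- nrow(state@centers)
    K <- ncol(state@centers)
    labels <- sample.int(J, n, replace = TRUE)
    u <- stats::rgamma(n, shape = state@dof / 2, rate = state@dof / 2)
    E <- matrix(stats::rnorm(n * K), n, K) / sqrt(u)
    samples <- state@centers[labels, , drop = FALSE] +
      E * sqrt(state@scaleDiags[labels, , drop = FALSE])
    list(samples = samples, labels = labels)
  })
}
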