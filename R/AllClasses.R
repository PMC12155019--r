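#' @import methods
NULL

#' Student's t-mixture state
#'
#' Parameters of a `J`-component multivariate Student's t-mixture with
#' diagonal scale matrices and equal mixing weights `1/J`: per-cluster
#' centers \eqn{\mu_j} (rows of `centers`), the diagonal entries of the
#' per-cluster scale matrices \eqn{\Sigma_j} (rows of `scaleDiags`), and a
#' single shared degrees-of-freedom \eqn{\nu}. The degrees of freedom must
#' exceed 2 so that the component variance \eqn{\nu/(\nu-2)\,\Sigma_j} is
#' defined; the default used throughout the package is 2.1, just above that
#' threshold. `clampFloor` is the numerical floor applied to every scale
#' entry to keep high-dimensional scale matrices away from singularity.
#'
#' @slot centers J x K numeric matrix of cluster centers.
#' @slot scaleDiags J x K numeric matrix of strictly positive scale diagonals.
#' @slot dof degrees of freedom, a single numeric > 2.
#' @slot clampFloor positive numeric floor on `scaleDiags` entries.
#'
#' @seealso [tMixtureState()], [eStep()], [mStep()], [initClusters()]
#' @export
setClass("TMixtureState",
  representation(
    centers = "matrix",
    scaleDiags = "matrix",
    dof = "numeric",
    clampFloor = "numeric"
  )
)

setValidity("TMixtureState", function(object) {
  msg <- character()
  if (!identical(dim(object@centers), dim(object@scaleDiags))) {
    msg <- c(msg, "'centers' and 'scaleDiags' must have identical shape")
  }
  if (nrow(object@centers) < 1L) msg <- c(msg, "need at least one cluster")
  if (length(object@dof) != 1L || object@dof <= 2) {
    msg <- c(msg, "'dof' must be a single value > 2 (finite component variance)")
  }
  if (length(object@clampFloor) != 1L || object@clampFloor <= 0) {
    msg <- c(msg, "'clampFloor' must be a single positive value")
  }
  if (length(msg) == 0 && any(object@scaleDiags < object@clampFloor)) {
    msg <- c(msg, "every 'scaleDiags' entry must be >= 'clampFloor'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a t-mixture state
#'
#' @param centers J x K matrix of cluster centers.
#' @param scaleDiags J x K matrix of positive scale diagonals; entries below
#'   `clampFloor` are raised to the floor.
#' @param dof shared degrees of freedom (> 2); default 2.1.
#' @param clampFloor numerical floor for scale entries; default `1e-6`.
#' @return a [TMixtureState-class] object.
#' @export
#' @examples
#' st <- tMixtureState(centers = rbind(c(0, 0), c(3, 3)),
#'                     scaleDiags = rbind(c(1, 1), c(1, 2)))
#' st
tMixtureState <- function(centers, scaleDiags, dof = 2.1, clampFloor = 1e-6) {
  centers <- as.matrix(centers)
  scaleDiags <- as.matrix(scaleDiags)
  if (any(scaleDiags <= 0)) {
    stop("scale matrix diagonals must be strictly positive", call. = FALSE)
  }
  scaleDiags <- pmax(scaleDiags, clampFloor)
  new("TMixtureState", centers = centers, scaleDiags = scaleDiags,
      dof = dof, clampFloor = clampFloor)
}

#' Stimulus-response dataset
#'
#' Container for stimuli paired with per-neuron response vectors, plus the
#' ground truth that only synthetic data carry: the generating cluster
#' labels and the true readout weights. `stimuli` is either a B x K matrix
#' (linear-neuron setting) or a B x H x W x C array (core-readout setting);
#' `responses` is always B x N with finite entries.
#'
#' @slot stimuli numeric matrix or 4-d array, first dimension B.
#' @slot responses B x N numeric matrix (nonnegative counts in the Poisson setting; signed in the linear-neuron setting).
#' @slot trueLabels integer vector of length N, or length 0 when unknown.
#' @slot trueWeights N x K matrix of generating weights, or 0 x 0.
#' @slot truePositions N x 2 matrix of generating readout positions, or 0 x 0.
#' @slot behavior B x 3 matrix of behavioral covariates, or 0 x 0 (interface
#'   hook; no bundled experiment uses it).
#' @export
setClass("StimulusResponseDataset",
  representation(
    stimuli = "array",
    responses = "matrix",
    trueLabels = "integer",
    trueWeights = "matrix",
    truePositions = "matrix",
    behavior = "matrix"
  )
)

setValidity("StimulusResponseDataset", function(object) {
  msg <- character()
  B <- dim(object@stimuli)[1L]
  if (nrow(object@responses) != B) {
    msg <- c(msg, "stimuli and responses must agree in the number of trials")
  }
  if (any(!is.finite(object@responses))) {
    msg <- c(msg, "responses must be finite")
  }
  N <- ncol(object@responses)
  if (length(object@trueLabels) && length(object@trueLabels) != N) {
    msg <- c(msg, "trueLabels length must equal the number of neurons")
  }
  if (nrow(object@trueWeights) && nrow(object@trueWeights) != N) {
    msg <- c(msg, "trueWeights rows must equal the number of neurons")
  }
  if (length(msg)) msg else TRUE
})

stimulusResponseDataset <- function(stimuli, responses,
                                    trueLabels = integer(0),
                                    trueWeights = matrix(0, 0, 0),
                                    truePositions = matrix(0, 0, 0),
                                    behavior = matrix(0, 0, 0)) {
  new("StimulusResponseDataset",
      stimuli = stimuli, responses = responses,
      trueLabels = as.integer(trueLabels), trueWeights = trueWeights,
      truePositions = truePositions, behavior = behavior)
}

#' Training configuration
#'
#' All tunables of the joint training loop. `beta` weighs the clustering
#' loss against the predictive loss; `pretrainEpochs` is the number of
#' epochs trained on the predictive loss alone before clusters are
#' initialized; `dof` is the shared t-mixture degrees of freedom (2.1 by
#' default, the smallest value at which the component variance is defined
#' up to one decimal); `clampFloor` is the scale-matrix floor.
#'
#' @slot beta nonnegative clustering-loss weight.
#' @slot pretrainEpochs integer >= 0.
#' @slot totalEpochs integer >= pretrainEpochs; epochs including pretraining.
#' @slot learningRate positive step size for the Adam optimizer.
#' @slot batchSize integer minibatch size.
#' @slot numClusters integer J >= 1.
#' @slot dof degrees of freedom > 2.
#' @slot clampFloor positive scale floor.
#' @slot seed integer master seed; fans out to named streams.
#' @slot modelKind `"linear-toy"` or `"core-readout"`.
#' @slot l2Readout L2 penalty coefficient on readout weights (core-readout
#'   predictive loss only).
#' @slot patience early-stopping patience in epochs (0 disables).
#' @export
setClass("TrainConfig",
  representation(
    beta = "numeric", pretrainEpochs = "integer", totalEpochs = "integer",
    learningRate = "numeric", batchSize = "integer", numClusters = "integer",
    dof = "numeric", clampFloor = "numeric", seed = "integer",
    modelKind = "character", l2Readout = "numeric", patience = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@beta < 0) msg <- c(msg, "'beta' must be >= 0")
  if (object@pretrainEpochs < 0) msg <- c(msg, "'pretrainEpochs' must be >= 0")
  if (object@totalEpochs < object@pretrainEpochs) {
    msg <- c(msg, "'totalEpochs' must be >= 'pretrainEpochs'")
  }
  if (object@learningRate <= 0) msg <- c(msg, "'learningRate' must be > 0")
  if (object@batchSize < 1) msg <- c(msg, "'batchSize' must be >= 1")
  if (object@numClusters < 1) msg <- c(msg, "'numClusters' must be >= 1")
  if (object@dof <= 2) msg <- c(msg, "'dof' must be > 2 (finite variance)")
  if (object@clampFloor <= 0) msg <- c(msg, "'clampFloor' must be > 0")
  if (!object@modelKind %in% c("linear-toy", "core-readout")) {
    msg <- c(msg, "'modelKind' must be 'linear-toy' or 'core-readout'")
  }
  if (length(msg)) msg else TRUE
})

#' Linear-neuron model
#'
#' The simplest embedding model: each neuron's response to a stimulus
#' vector is the inner product of its weight row with the stimulus,
#' \eqn{y_i = z_i^\top x}. The weight matrix is the embedding matrix.
#'
#' @slot weights N x K numeric matrix of per-neuron weights.
#' @export
setClass("LinearNeuronModel", representation(weights = "matrix"))

#' Miniature core-readout model
#'
#' A shared two-layer convolutional core maps each stimulus to an
#' H x W x K feature space; per-neuron Gaussian readouts bilinearly
#' interpolate the feature map at the neuron's receptive-field position
#' `(x_i, y_i)` in normalized coordinates and weight the resulting
#' K-vector by the neuron's embedding; a shifted softplus maps the
#' weighted sum to a strictly positive firing rate.
#'
#' @slot coreParams named list of convolution kernels and biases
#'   (`W1`, `b1`, `W2`, `b2`).
#' @slot positions N x 2 matrix of readout positions in `[-1, 1]^2`.
#' @slot weights N x K matrix of readout weights (the functional embeddings).
#' @export
setClass("CoreReadoutModel",
  representation(coreParams = "list", positions = "matrix", weights = "matrix")
)

setValidity("CoreReadoutModel", function(object) {
  msg <- character()
  if (nrow(object@positions) != nrow(object@weights)) {
    msg <- c(msg, "positions and weights must have one row per neuron")
  }
  if (ncol(object@positions) != 2L) msg <- c(msg, "positions must be N x 2")
  if (length(object@positions) && max(abs(object@positions)) > 1 + 1e-12) {
    msg <- c(msg, "positions must lie in [-1, 1]^2")
  }
  if (!all(c("W1", "b1", "W2", "b2") %in% names(object@coreParams))) {
    msg <- c(msg, "coreParams must contain W1, b1, W2, b2")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a joint training run
#'
#' @slot model the trained model object.
#' @slot state final [TMixtureState-class] (slot may be an empty state when
#'   clustering never ran, e.g. pure pretraining).
#' @slot log per-epoch data.frame with columns `epoch`, `phase`,
#'   `modelLoss`, `clusterLoss`, `totalLoss`, `valMetric`.
#' @slot mapLabels integer MAP cluster label per neuron.
#' @slot seed master seed of the run.
#' @export
setClass("TrainResult",
  representation(
    model = "ANY", state = "ANY", log = "data.frame",
    mapLabels = "integer", seed = "integer"
  )
)
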