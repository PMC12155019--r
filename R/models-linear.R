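#' Construct a linear-neuron model
#'
#' @param weights N x K matrix of per-neuron weights, or `NULL` to
#'   initialize `nNeurons` x `dim` weights as small Gaussian noise.
#' @param nNeurons,dim shape used when `weights` is `NULL`.
#' @param seed seed for the random initialization.
#' @return a [LinearNeuronModel-class].
#' @export
#' @examples
#' m <- linearNeuronModel(nNeurons = 5, dim = 3, seed = 1)
#' linearPredict(m, diag(3))
linearNeuronModel <- function(weights = NULL, nNeurons = NULL, dim = NULL,
                              seed = 1L) {
  if (is.null(weights)) {
    stopifnot(!is.null(nNeurons), !is.null(dim))
    weights <- withStream(seed, "init",
                          matrix(stats::rnorm(nNeurons * dim, sd = 0.01),
                                 nNeurons, dim))
  }
  new("LinearNeuronModel", weights = as.matrix(weights))
}

#' Predict linear-neuron responses
#'
#' `output[b, i]` is the inner product of neuron `i`'s weight row with
#' stimulus row `b`.
#'
#' @param model a [LinearNeuronModel-class].
#' @param stimuli B x K stimulus matrix.
#' @return B x N response matrix.
#' @export
linearPredict <- function(model, stimuli) {
  stimuli <- as.matrix(stimuli)
  if (ncol(stimuli) != ncol(model@weights)) {
    stop(sprintf("stimuli have %d columns but model weights have %d",
                 ncol(stimuli), ncol(model@weights)), call. = FALSE)
  }
  stimuli %*% t(model@weights)
}

#' @rdname linearPredict
#' @export
setMethod("predictResponses", "LinearNeuronModel",
          function(model, stimuli) linearPredict(model, stimuli))

#' Mean squared error
#'
#' @param predicted,observed matrices of identical shape.
#' @return mean of squared differences over all entries.
#' @export
mseLoss <- function(predicted, observed) {
  if (!identical(dim(predicted), dim(observed))) {
    stop("'predicted' and 'observed' must have identical shape", call. = FALSE)
  }
  mean((predicted - observed)^2)
}

# gradient of mseLoss w.r.t. the weight matrix of a linear model
mseGradWeights <- function(model, stimuli, observed) {
  pred <- linearPredict(model, stimuli)
  (2 / length(pred)) * crossprod(pred - observed, stimuli)
}

#' Poisson response loss
#'
#' \deqn{L_P = \frac1N \sum_{l=1}^{L} \sum_{i=1}^{N}
#'   \left(\hat r_{il} - r_{il} \log \hat r_{il}\right)}
#' summed over images and normalized by the number of neurons only, the
#' negative Poisson log-likelihood up to the \eqn{\log r!} constant.
#'
#' @param predicted B x N matrix of strictly positive predicted rates.
#' @param observed B x N matrix of nonnegative observed responses.
#' @return scalar loss.
#' @export
poissonLoss <- function(predicted, observed) {
  if (!identical(dim(predicted), dim(observed))) {
    stop("'predicted' and 'observed' must have identical shape", call. = FALSE)
  }
  if (any(predicted <= 0)) {
    stop("predicted rates must be strictly positive", call. = FALSE)
  }
  sum(predicted - observed * log(predicted)) / ncol(predicted)
}
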