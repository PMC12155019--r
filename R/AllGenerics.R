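#' Accessors for mixture states, models, datasets and results
#'
#' `centers()`, `scaleDiags()`, `dof()`, `clampFloor()` and `numClusters()`
#' read the slots of a [TMixtureState-class]. `embeddings()` returns the
#' N x K matrix of per-neuron functional embeddings of a model (the weight
#' matrix of a [LinearNeuronModel-class], the readout weights of a
#' [CoreReadoutModel-class]). `stimuli()`, `responses()`, `trueLabels()`
#' and `trueWeights()` read a [StimulusResponseDataset-class]. `trainLog()`,
#' `mixtureState()` and `mapLabels()` read a [TrainResult-class].
#'
#' @param object the object to access.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases centers scaleDiags dof clampFloor numClusters embeddings
#'   stimuli responses trueLabels trueWeights trainLog mixtureState mapLabels
NULL

#' @rdname accessors
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))
#' @rdname accessors
#' @export
setGeneric("scaleDiags", function(object) standardGeneric("scaleDiags"))
#' @rdname accessors
#' @export
setGeneric("dof", function(object) standardGeneric("dof"))
#' @rdname accessors
#' @export
setGeneric("clampFloor", function(object) standardGeneric("clampFloor"))
#' @rdname accessors
#' @export
setGeneric("numClusters", function(object) standardGeneric("numClusters"))
#' @rdname accessors
#' @export
setGeneric("embeddings", function(object) standardGeneric("embeddings"))
#' @rdname accessors
#' @export
setGeneric("stimuli", function(object) standardGeneric("stimuli"))
#' @rdname accessors
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("trueWeights", function(object) standardGeneric("trueWeights"))
#' @rdname accessors
#' @export
setGeneric("trainLog", function(object) standardGeneric("trainLog"))
#' @rdname accessors
#' @export
setGeneric("mixtureState", function(object) standardGeneric("mixtureState"))
#' @rdname accessors
#' @export
setGeneric("mapLabels", function(object) standardGeneric("mapLabels"))

#' Predict responses of an embedding model
#'
#' @param model a [LinearNeuronModel-class] or [CoreReadoutModel-class].
#' @param stimuli stimulus matrix/array matching the model's input contract.
#' @return B x N matrix of predicted responses.
#' @export
setGeneric("predictResponses",
           function(model, stimuli) standardGeneric("predictResponses"))

#' @rdname accessors
#' @export
setMethod("centers", "TMixtureState", function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("scaleDiags", "TMixtureState", function(object) object@scaleDiags)
#' @rdname accessors
#' @export
setMethod("dof", "TMixtureState", function(object) object@dof)
#' @rdname accessors
#' @export
setMethod("clampFloor", "TMixtureState", function(object) object@clampFloor)
#' @rdname accessors
#' @export
setMethod("numClusters", "TMixtureState", function(object) nrow(object@centers))

#' @rdname accessors
#' @export
setMethod("embeddings", "LinearNeuronModel", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("embeddings", "CoreReadoutModel", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("stimuli", "StimulusResponseDataset", function(object) object@stimuli)
#' @rdname accessors
#' @export
setMethod("responses", "StimulusResponseDataset", function(object) object@responses)
#' @rdname accessors
#' @export
setMethod("trueLabels", "StimulusResponseDataset", function(object) object@trueLabels)
#' @rdname accessors
#' @export
setMethod("trueWeights", "StimulusResponseDataset", function(object) object@trueWeights)

#' @rdname accessors
#' @export
setMethod("trainLog", "TrainResult", function(object) object@log)
#' @rdname accessors
#' @export
setMethod("mixtureState", "TrainResult", function(object) object@state)
#' @rdname accessors
#' @export
setMethod("mapLabels", "TrainResult", function(object) object@mapLabels)
#' @rdname accessors
#' @export
setMethod("embeddings", "TrainResult", function(object) embeddings(object@model))

setMethod("show", "TMixtureState", function(object) {
  cat(sprintf("TMixtureState: %d clusters in %d dimensions, nu = %g, floor = %g\n",
              nrow(object@centers), ncol(object@centers), object@dof,
              object@clampFloor))
  cat("center norms:", paste(signif(sqrt(rowSums(object@centers^2)), 4),
                             collapse = ", "), "\n")
})

setMethod("show", "StimulusResponseDataset", function(object) {
  d <- dim(object@stimuli)
  cat(sprintf("StimulusResponseDataset: %d trials x %d neurons; stimuli [%s]%s\n",
              d[1L], ncol(object@responses), paste(d, collapse = " x "),
              if (length(object@trueLabels)) {
                sprintf("; %d planted clusters",
                        length(unique(object@trueLabels)))
              } else ""))
})

setMethod("show", "LinearNeuronModel", function(object) {
  cat(sprintf("LinearNeuronModel: %d neurons, %d-dimensional embeddings\n",
              nrow(object@weights), ncol(object@weights)))
})

setMethod("show", "CoreReadoutModel", function(object) {
  cat(sprintf(
    "CoreReadoutModel: %d neurons, %d-dimensional embeddings, %d core channels\n",
    nrow(object@weights), ncol(object@weights),
    dim(object@coreParams$W2)[4L]))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig(%s): beta = %g, epochs %d (+%d pretrain), lr = %g, J = %d, nu = %g\n",
    object@modelKind, object@beta, object@totalEpochs, object@pretrainEpochs,
    object@learningRate, object@numClusters, object@dof))
})

setMethod("show", "TrainResult", function(object) {
  cat(sprintf("TrainResult: %d epochs logged, seed %d\n",
              nrow(object@log), object@seed))
  if (length(object@mapLabels)) {
    tab <- table(object@mapLabels)
    cat("MAP cluster sizes:", paste(sprintf("%s:%d", names(tab), tab),
                                    collapse = ", "), "\n")
  }
})
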