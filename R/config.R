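configFields <- c("beta", "pretrainEpochs", "totalEpochs", "learningRate",
                  "batchSize", "numClusters", "dof", "clampFloor", "seed",
                  "modelKind", "l2Readout", "patience")

#' Construct a training configuration
#'
#' All arguments have defaults; see [TrainConfig-class] for their meaning.
#' `dof` defaults to 2.1, just above the `dof > 2` threshold at which the
#' t-component variance exists; `clampFloor` defaults to `1e-6`, matching
#' the variance regularization of the GMM baseline.
#'
#' @param beta clustering-loss weight (>= 0).
#' @param pretrainEpochs epochs of model-loss-only pretraining.
#' @param totalEpochs total epochs including pretraining.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param numClusters number of clusters J.
#' @param dof t-mixture degrees of freedom (> 2).
#' @param clampFloor scale-matrix floor.
#' @param seed master seed; fans out to named streams via [deriveSeed()].
#' @param modelKind `"linear-toy"` or `"core-readout"`.
#' @param l2Readout L2 coefficient on readout weights (core-readout only).
#' @param patience early-stopping patience in epochs; 0 disables early
#'   stopping and learning-rate decay.
#' @return a [TrainConfig-class] object.
#' @export
#' @examples
#' trainConfig(beta = 10, numClusters = 3)
trainConfig <- function(beta = 1, pretrainEpochs = 10L, totalEpochs = 35L,
                        learningRate = 0.01, batchSize = 256L,
                        numClusters = 2L, dof = 2.1, clampFloor = 1e-6,
                        seed = 1L, modelKind = "linear-toy",
                        l2Readout = 1e-4, patience = 0L) {
  new("TrainConfig", beta = as.numeric(beta),
      pretrainEpochs = as.integer(pretrainEpochs),
      totalEpochs = as.integer(totalEpochs),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize),
      numClusters = as.integer(numClusters), dof = as.numeric(dof),
      clampFloor = as.numeric(clampFloor), seed = as.integer(seed),
      modelKind = modelKind, l2Readout = as.numeric(l2Readout),
      patience = as.integer(patience))
}

#' Read and write training configurations as YAML
#'
#' `loadConfig()` fills unspecified fields with the [trainConfig()]
#' defaults, rejects unknown keys and validates every constraint with a
#' field-level message; an empty file yields the full default
#' configuration. `saveConfig()` writes a configuration that round-trips
#' through `loadConfig()` unchanged.
#'
#' @param path file path of a YAML config.
#' @param config a [TrainConfig-class].
#' @return `loadConfig()` returns a [TrainConfig-class]; `saveConfig()`
#'   returns `path` invisibly.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), configFields)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- tryCatch(do.call(trainConfig, vals), error = function(e) {
    stop(sprintf("invalid config '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  cfg
}

#' @rdname loadConfig
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "TrainConfig"))
  vals <- lapply(configFields, function(f) slot(config, f))
  names(vals) <- configFields
  yaml::write_yaml(vals, path, precision = 17L)
  invisible(path)
}
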