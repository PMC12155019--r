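#' Read and write embedding matrices as TSV
#'
#' One row per neuron, with a `neuron_id` column followed by feature
#' columns `f0..f{K-1}`.
#'
#' @param Z N x K embedding matrix.
#' @param path TSV file path.
#' @return `readEmbeddings()` returns the N x K matrix (neuron ids as row
#'   names); `writeEmbeddings()` returns `path` invisibly.
#' @export
writeEmbeddings <- function(Z, path) {
  Z <- as.matrix(Z)
  df <- data.frame(neuron_id = if (is.null(rownames(Z))) seq_len(nrow(Z)) - 1L
                   else rownames(Z), Z)
  names(df) <- c("neuron_id", paste0("f", seq_len(ncol(Z)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "neuron_id") {
    stop("embedding TSV must start with a 'neuron_id' column", call. = FALSE)
  }
  Z <- as.matrix(df[, -1L, drop = FALSE])
  rownames(Z) <- df$neuron_id
  Z
}

#' Serialize a mixture state to structured text
#'
#' Writes centers, scale diagonals, degrees of freedom, cluster count and
#' clamp floor as JSON with full double precision; `readMixtureState()`
#' reconstructs a bit-identical [TMixtureState-class].
#'
#' @param state a [TMixtureState-class].
#' @param path JSON file path.
#' @return `readMixtureState()` returns the state; `writeMixtureState()`
#'   returns `path` invisibly.
#' @export
writeMixtureState <- function(state, path) {
  stopifnot(is(state, "TMixtureState"))
  # doubles are stored as %.17g strings: 17 significant digits
  # round-trip every IEEE double bit-exactly
  fmt <- function(x) {
    m <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
    apply(m, 1L, identity, simplify = FALSE)
  }
  jsonlite::write_json(
    list(numClusters = nrow(state@centers),
         dof = sprintf("%.17g", state@dof),
         clampFloor = sprintf("%.17g", state@clampFloor),
         centers = fmt(state@centers),
         scaleDiags = fmt(state@scaleDiags)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeMixtureState
#' @export
readMixtureState <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(m) {
    if (is.list(m)) m <- do.call(rbind, m)
    matrix(as.numeric(m), nrow(m), ncol(m))
  }
  st <- new("TMixtureState",
            centers = toMat(x$centers),
            scaleDiags = toMat(x$scaleDiags),
            dof = as.numeric(x$dof), clampFloor = as.numeric(x$clampFloor))
  if (nrow(st@centers) != x$numClusters) {
    stop("corrupt mixture state: cluster count mismatch", call. = FALSE)
  }
  st
}

#' Save and load datasets and model checkpoints
#'
#' Native R serialization of [StimulusResponseDataset-class] objects and
#' model objects (all parameters keyed by name).
#'
#' @param object the dataset or model.
#' @param path file path (`.rds`).
#' @return `loadArtifact()` returns the object; `saveArtifact()` returns
#'   `path` invisibly.
#' @export
saveArtifact <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveArtifact
#' @export
loadArtifact <- function(path) readRDS(path)

# md5 digests of a set of files, for run manifests
fileDigests <- function(paths) {
  paths <- paths[file.exists(paths)]
  d <- tools::md5sum(paths)
  as.list(stats::setNames(unname(d), basename(paths)))
}

#' Write a run manifest
#'
#' Records the configuration snapshot, resolved per-stream seeds, package
#' version, output-file digests and a wall-clock stamp, so that a
#' deterministic run can be reproduced bit-identically from its manifest.
#'
#' @param path JSON file path.
#' @param config a [TrainConfig-class].
#' @param outputs character vector of output file paths to digest.
#' @param extra named list of additional fields.
#' @return the manifest list, invisibly.
#' @export
writeManifest <- function(path, config, outputs = character(0),
                          extra = list()) {
  streams <- c("data", "init", "kmeans", "batch-1", "counts", "tmm")
  manifest <- c(list(
    package = "decembr",
    version = as.character(utils::packageVersion("decembr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = stats::setNames(lapply(configFields, function(f)
      slot(config, f)), configFields),
    seeds = stats::setNames(lapply(streams, function(s)
      deriveSeed(config@seed, s)), streams),
    outputs = fileDigests(outputs)), extra)
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
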