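## Delimited-text readers/writers for spike/stimulus matrices, JSON + TSV
## serialization of network models, and run configuration.

#' Read a spike-count or stimulus matrix
#'
#' Tab- or comma-delimited text with a header row of source identifiers;
#' rows are time bins.  Spike files must contain non-negative integers,
#' stimulus files 0/1 indicators; violations are reported with their row
#' and column.
#'
#' @param path file path.
#' @param kind "spikes" or "stimuli".
#' @param sep field separator (default tab).
#' @return Labeled numeric matrix.
#' @export
readMatrix <- function(path, kind = c("spikes", "stimuli"), sep = "\t") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric entries in ", path)
  bad <- if (kind == "spikes") {
    which(mat < 0 | mat != round(mat), arr.ind = TRUE)
  } else {
    which(mat != 0 & mat != 1, arr.ind = TRUE)
  }
  if (nrow(bad) > 0) {
    stop(sprintf("invalid %s entry %g at row %d, column '%s' in %s",
                 kind, mat[bad[1, , drop = FALSE]], bad[1, 1],
                 colnames(mat)[bad[1, 2]], path))
  }
  if (kind == "spikes") storage.mode(mat) <- "integer"
  mat
}

#' @rdname readMatrix
#' @param mat matrix to write.
#' @export
writeMatrix <- function(mat, path, sep = "\t") {
  write.table(mat, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SpikeExperiment from a pair of delimited files
#'
#' @param spikesPath,stimuliPath file paths.
#' @param sep field separator.
#' @return A \linkS4class{SpikeExperiment}.
#' @export
readSpikeExperiment <- function(spikesPath, stimuliPath, sep = "\t") {
  spikeExperiment(readMatrix(spikesPath, "spikes", sep),
                  readMatrix(stimuliPath, "stimuli", sep))
}

#' Write / read a network model
#'
#' JSON serialization (kappa, windows, biases, and an edge list with
#' source type, source id, target neuron and weight).  Weights are
#' written with 17 significant digits so the round trip preserves them
#' to the last bit.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param path output path (.json).
#' @return \code{writeNetworkModel}: the path, invisibly;
#'   \code{readNetworkModel}: the restored model.
#' @export
writeNetworkModel <- function(model, path) {
  eW <- which(model@W != 0, arr.ind = TRUE)
  eH <- which(model@H != 0, arr.ind = TRUE)
  edges <- rbind(
    if (nrow(eW)) data.frame(source_type = "neuron", source_id = eW[, 1],
                             target_neuron = eW[, 2],
                             weight = model@W[eW], stringsAsFactors = FALSE),
    if (nrow(eH)) data.frame(source_type = "stimulus", source_id = eH[, 1],
                             target_neuron = eH[, 2],
                             weight = model@H[eH], stringsAsFactors = FALSE))
  obj <- list(kappa = model@kappa,
              n_neurons = nNeurons(model), n_stimuli = nStimuli(model),
              spike_window = c(model@spikeWindow@lower, model@spikeWindow@upper),
              stim_window = c(model@stimWindow@lower, model@stimWindow@upper),
              biases = model@biases,
              edges = if (is.null(edges)) list() else edges)
  if (is(model, "GroundTruthNetwork")) {
    obj$clusters <- model@clusters
    obj$params <- model@params[!vapply(model@params, is.null, logical(1))]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeNetworkModel
#' @export
readNetworkModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("kappa", "n_neurons", "n_stimuli", "spike_window",
              "stim_window", "biases"))
    if (is.null(obj[[f]])) stop("model file missing field '", f, "': ", path)
  nc <- obj$n_neurons; ns <- obj$n_stimuli
  W <- matrix(0, nc, nc)
  H <- matrix(0, ns, nc)
  ed <- obj$edges
  if (length(ed) && nrow(as.data.frame(ed)) > 0) {
    ed <- as.data.frame(ed)
    isN <- ed$source_type == "neuron"
    if (any(isN)) W[cbind(ed$source_id[isN], ed$target_neuron[isN])] <- ed$weight[isN]
    if (any(!isN)) H[cbind(ed$source_id[!isN], ed$target_neuron[!isN])] <- ed$weight[!isN]
  }
  base <- networkModel(W, H, obj$biases, obj$kappa,
                       boxcarWindow(obj$spike_window[1], obj$spike_window[2]),
                       boxcarWindow(obj$stim_window[1], obj$stim_window[2]))
  if (!is.null(obj$clusters)) {
    base <- new("GroundTruthNetwork", base, clusters = as.integer(obj$clusters),
                params = as.list(obj$params))
  }
  base
}

#' Write a model's edge list as TSV
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param path output path (.tsv).
#' @export
writeEdgeList <- function(model, path) {
  eW <- which(model@W != 0, arr.ind = TRUE)
  eH <- which(model@H != 0, arr.ind = TRUE)
  edges <- rbind(
    data.frame(source_type = rep("neuron", nrow(eW)), source_id = eW[, 1],
               target_neuron = eW[, 2], weight = model@W[eW]),
    data.frame(source_type = rep("stimulus", nrow(eH)), source_id = eH[, 1],
               target_neuron = eH[, 2], weight = model@H[eH]))
  write.table(format(edges, digits = 17), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Validated bundle of every tunable: boxcar windows, kappa, the
#' selection parameters (gamma, nu, nSplits, kMax), the active-learning
#' parameters (beta, zClip, batch sizes) and seeds.  Unknown keys are
#' rejected on load.
#'
#' @param ... overrides of the defaults.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(...) {
  defaults <- list(
    kappa = 10, spikeWindowLower = 5L, spikeWindowUpper = 2L,
    stimWindowLower = 5L, stimWindowUpper = 2L,
    gamma = 0.01, nu = 0.7, nSplits = 10L, kMax = 5L, prescreen = FALSE,
    beta = 0.25, zClip = 2, ercHorizon = 2000L, ercReps = 5L,
    framesPerStimulus = 4L, batchSize = 500L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$kappa > 0, cfg$gamma > 0, cfg$gamma < 1, cfg$nu > 0,
            cfg$nu <= 1, cfg$nSplits >= 1, cfg$kMax >= 1, cfg$beta >= 0,
            cfg$beta <= 1, cfg$zClip > 0, cfg$batchSize >= 1)
  structure(cfg, class = "runConfig")
}

#' @rdname runConfig
#' @param path JSON file of configuration values.
#' @export
readRunConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, as.list(vals))
}

#' @rdname runConfig
#' @param cfg a \code{runConfig}.
#' @export
selectionConfigFrom <- function(cfg) {
  selectionConfig(gamma = cfg$gamma, kMax = cfg$kMax, nu = cfg$nu,
                  nSplits = cfg$nSplits, seed = cfg$seed,
                  prescreen = cfg$prescreen)
}

#' @rdname runConfig
#' @export
activeLearningConfigFrom <- function(cfg) {
  activeLearningConfig(beta = cfg$beta, zClip = cfg$zClip,
                       ercHorizon = cfg$ercHorizon, ercReps = cfg$ercReps,
                       framesPerStimulus = cfg$framesPerStimulus,
                       seed = cfg$seed)
}
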