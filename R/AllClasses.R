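#' @useDynLib SpikeNetGLM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats coef median pchisq pnorm qpois rnorm runif sd setNames
#' @importFrom utils combn read.table write.table
NULL

#' Boxcar influence window
#'
#' A rectangular (boxcar) influence function summing a source's activity
#' over the delay range \code{[t - lower, t - upper]} (inclusive), i.e. the
#' most recent contributing bin lags \code{upper} bins behind \code{t} and
#' the oldest lags \code{lower} bins.
#'
#' @slot lower integer, oldest contributing lag (must be >= upper).
#' @slot upper integer, most recent contributing lag (>= 1).
#' @export
setClass("BoxcarWindow", representation(lower = "integer", upper = "integer"))

setValidity("BoxcarWindow", function(object) {
  if (length(object@lower) != 1L || length(object@upper) != 1L)
    return("lower and upper must be scalars")
  if (is.na(object@lower) || is.na(object@upper))
    return("window delays must not be NA")
  if (object@upper < 1L) return("upper delay must be >= 1")
  if (object@lower < object@upper) return("lower delay must be >= upper delay")
  TRUE
})

#' Construct a boxcar window
#'
#' @param lower oldest contributing lag in bins.
#' @param upper most recent contributing lag in bins.
#' @return A \linkS4class{BoxcarWindow}.
#' @examples
#' boxcarWindow(5, 2)  # sums bins t-5 ... t-2
#' @export
boxcarWindow <- function(lower = 5L, upper = 2L) {
  new("BoxcarWindow", lower = as.integer(lower), upper = as.integer(upper))
}

#' @describeIn boxcarWindow window length in bins
#' @param window a \code{BoxcarWindow}.
#' @export
windowLength <- function(window) window@lower - window@upper + 1L

setMethod("show", "BoxcarWindow", function(object) {
  cat(sprintf("BoxcarWindow: bins t-%d ... t-%d\n", object@lower, object@upper))
})

#' Spike-count and stimulus time series
#'
#' Container for an acquisition: an integer spike-count matrix (time bins x
#' neurons) and a binary stimulus indicator matrix (time bins x stimuli)
#' recorded on the same clock.
#'
#' @slot spikes integer matrix, time bins x neurons, non-negative counts.
#' @slot stimuli numeric matrix of 0/1 indicators, time bins x stimuli.
#' @slot binDuration informational bin duration (seconds); not used in fits.
#' @export
setClass("SpikeExperiment",
         representation(spikes = "matrix", stimuli = "matrix",
                        binDuration = "numeric"))

setValidity("SpikeExperiment", function(object) {
  sp <- object@spikes; st <- object@stimuli
  if (nrow(sp) < 1L || ncol(sp) < 1L) return("spikes must have >= 1 row and column")
  if (nrow(st) != nrow(sp)) return("spikes and stimuli must cover the same time bins")
  if (anyNA(sp) || anyNA(st)) return("NA entries are not allowed")
  if (any(sp < 0) || any(sp != round(sp))) return("spike counts must be non-negative integers")
  if (!all(st %in% c(0, 1))) return("stimulus indicators must be 0/1")
  TRUE
})

#' Construct a SpikeExperiment
#'
#' @param spikes time bins x neurons matrix of non-negative integer counts.
#' @param stimuli time bins x stimuli matrix of 0/1 indicators.
#' @param binDuration informational bin duration.
#' @return A \linkS4class{SpikeExperiment}.
#' @export
spikeExperiment <- function(spikes, stimuli, binDuration = NA_real_) {
  spikes <- as.matrix(spikes)
  stimuli <- as.matrix(stimuli)
  storage.mode(spikes) <- "integer"
  storage.mode(stimuli) <- "double"
  if (is.null(colnames(spikes))) colnames(spikes) <- paste0("n", seq_len(ncol(spikes)))
  if (is.null(colnames(stimuli))) colnames(stimuli) <- paste0("s", seq_len(ncol(stimuli)))
  new("SpikeExperiment", spikes = spikes, stimuli = stimuli,
      binDuration = binDuration)
}

#' @rdname spikeExperiment
#' @param object,x a \code{SpikeExperiment}.
#' @export
setGeneric("spikeCounts", function(object) standardGeneric("spikeCounts"))
#' @rdname spikeExperiment
#' @export
setMethod("spikeCounts", "SpikeExperiment", function(object) object@spikes)

#' @rdname spikeExperiment
#' @export
setGeneric("stimulusIndicators", function(object) standardGeneric("stimulusIndicators"))
#' @rdname spikeExperiment
#' @export
setMethod("stimulusIndicators", "SpikeExperiment", function(object) object@stimuli)

#' @rdname spikeExperiment
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))
#' @rdname spikeExperiment
#' @export
setMethod("nNeurons", "SpikeExperiment", function(object) ncol(object@spikes))

#' @rdname spikeExperiment
#' @export
setGeneric("nStimuli", function(object) standardGeneric("nStimuli"))
#' @rdname spikeExperiment
#' @export
setMethod("nStimuli", "SpikeExperiment", function(object) ncol(object@stimuli))

#' @rdname spikeExperiment
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname spikeExperiment
#' @export
setMethod("nBins", "SpikeExperiment", function(object) nrow(object@spikes))

setMethod("show", "SpikeExperiment", function(object) {
  cat(sprintf("SpikeExperiment: %d bins, %d neurons, %d stimuli\n",
              nBins(object), nNeurons(object), nStimuli(object)))
  cat(sprintf("  mean rate %.4f spikes/bin\n", mean(object@spikes)))
})

#' Append freshly acquired bins to an experiment
#'
#' Used by the active-learning loop: new rows are concatenated in time.
#'
#' @param object an existing \linkS4class{SpikeExperiment}.
#' @param more a \code{SpikeExperiment} with the same neurons/stimuli.
#' @return The concatenated \code{SpikeExperiment}.
#' @export
appendSamples <- function(object, more) {
  stopifnot(is(object, "SpikeExperiment"), is(more, "SpikeExperiment"))
  if (nNeurons(object) != nNeurons(more) || nStimuli(object) != nStimuli(more))
    stop("experiments have incompatible dimensions")
  spikeExperiment(rbind(object@spikes, more@spikes),
                  rbind(object@stimuli, more@stimuli),
                  binDuration = object@binDuration)
}

#' Regressor design matrix for the spiking GLM
#'
#' Boxcar-convolved spike columns, boxcar-convolved stimulus columns and a
#' trailing all-ones bias column.  The first \code{validFrom - 1} rows lack
#' full boxcar history and are excluded from every likelihood and Fisher
#' information sum.
#'
#' @slot matrix time bins x (neurons + stimuli + 1) design matrix.
#' @slot labels column labels ("n1", ..., "s1", ..., "bias").
#' @slot types column types ("neuron", "stimulus", "bias").
#' @slot validFrom first row with full history.
#' @slot spikeWindow,stimWindow the \linkS4class{BoxcarWindow}s used.
#' @export
setClass("RegressorDesign",
         representation(matrix = "matrix", labels = "character",
                        types = "character", validFrom = "integer",
                        spikeWindow = "BoxcarWindow", stimWindow = "BoxcarWindow"))

setValidity("RegressorDesign", function(object) {
  if (ncol(object@matrix) != length(object@labels)) return("labels/matrix mismatch")
  if (length(object@types) != length(object@labels)) return("types/labels mismatch")
  bias <- object@types == "bias"
  if (sum(bias) != 1L || object@labels[bias] != "bias" ||
      !all(object@matrix[, bias] == 1))
    return("design must end with a single all-ones bias column")
  if (object@validFrom < 1L || object@validFrom > nrow(object@matrix) + 1L)
    return("validFrom out of range")
  TRUE
})

setMethod("show", "RegressorDesign", function(object) {
  cat(sprintf("RegressorDesign: %d bins (%d valid), %d neuron + %d stimulus regressors\n",
              nrow(object@matrix), nrow(object@matrix) - object@validFrom + 1L,
              sum(object@types == "neuron"), sum(object@types == "stimulus")))
})

#' Single-neuron GLM fit
#'
#' Maximum-likelihood fit of one neuron's spike train on a regressor subset:
#' estimated weights and bias, log-likelihood, observed Fisher information,
#' per-parameter Wald p-values, and BIC.
#'
#' @slot theta named estimate; parent weights first, bias last.
#' @slot parentSet regressor labels in the model (bias excluded).
#' @slot logLik maximized log-likelihood (additive constant -log(X!) dropped,
#'   so values are comparable only within this package).
#' @slot fisher observed Fisher information at the estimate.
#' @slot pValues per-parameter Wald p-values (chi-square with 1 df).
#' @slot bic \code{log(mValid) * |parentSet| - 2 * logLik}.
#' @slot mValid number of likelihood-contributing bins.
#' @slot converged optimizer status.
#' @slot iterations Newton iterations used.
#' @export
setClass("NeuronFit",
         representation(theta = "numeric", parentSet = "character",
                        logLik = "numeric", fisher = "matrix",
                        pValues = "numeric", bic = "numeric",
                        mValid = "integer", converged = "logical",
                        iterations = "integer"))

setValidity("NeuronFit", function(object) {
  p <- length(object@parentSet) + 1L
  if (length(object@theta) != p) return("theta must hold parent weights plus bias")
  if (!isTRUE(all.equal(object@fisher, t(object@fisher), tolerance = 1e-6)))
    return("fisher must be symmetric")
  if (any(object@pValues < 0 | object@pValues > 1)) return("p-values must lie in [0, 1]")
  TRUE
})

setMethod("show", "NeuronFit", function(object) {
  cat(sprintf("NeuronFit: %d parents, logLik %.3f, BIC %.3f, %s\n",
              length(object@parentSet), object@logLik, object@bic,
              if (object@converged) "converged" else "NOT converged"))
})

#' Directed network model
#'
#' Per-neuron biases plus the inter-neuron weight matrix \code{W} (entry
#' \code{[i, c]} is the influence of neuron i's boxcar-summed past activity
#' on neuron c) and the stimulus response matrix \code{H} (entry
#' \code{[s, c]} is the influence of stimulus s).  Zero means no edge.
#'
#' @slot W neurons x neurons weight matrix.
#' @slot H stimuli x neurons weight matrix.
#' @slot biases per-neuron bias.
#' @slot kappa softplus nonlinearity calibration constant.
#' @slot spikeWindow,stimWindow boxcar windows.
#' @export
setClass("NetworkModel",
         representation(W = "matrix", H = "matrix", biases = "numeric",
                        kappa = "numeric", spikeWindow = "BoxcarWindow",
                        stimWindow = "BoxcarWindow"))

setValidity("NetworkModel", function(object) {
  nc <- length(object@biases)
  if (nrow(object@W) != nc || ncol(object@W) != nc) return("W must be neurons x neurons")
  if (ncol(object@H) != nc) return("H must be stimuli x neurons")
  if (!all(is.finite(object@W)) || !all(is.finite(object@H)) ||
      !all(is.finite(object@biases))) return("weights must be finite")
  if (length(object@kappa) != 1L || object@kappa <= 0) return("kappa must be a positive scalar")
  TRUE
})

#' Construct a NetworkModel
#'
#' @param W neurons x neurons weight matrix (zero = no edge).
#' @param H stimuli x neurons weight matrix.
#' @param biases per-neuron bias vector.
#' @param kappa nonlinearity constant (default 10).
#' @param spikeWindow,stimWindow \linkS4class{BoxcarWindow}s.
#' @return A \linkS4class{NetworkModel}.
#' @export
networkModel <- function(W, H, biases, kappa = 10,
                         spikeWindow = boxcarWindow(5, 2),
                         stimWindow = boxcarWindow(5, 2)) {
  W <- as.matrix(W); H <- as.matrix(H)
  nc <- length(biases)
  if (is.null(rownames(W))) dimnames(W) <- list(paste0("n", 1:nc), paste0("n", 1:nc))
  if (is.null(rownames(H)))
    dimnames(H) <- list(paste0("s", seq_len(nrow(H))), paste0("n", 1:nc))
  new("NetworkModel", W = W, H = H, biases = as.numeric(biases),
      kappa = as.numeric(kappa), spikeWindow = spikeWindow,
      stimWindow = stimWindow)
}

#' @rdname networkModel
#' @param object a \code{NetworkModel}.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))
#' @rdname networkModel
#' @export
setMethod("weightMatrix", "NetworkModel", function(object) object@W)

#' @rdname networkModel
#' @export
setGeneric("stimulusWeights", function(object) standardGeneric("stimulusWeights"))
#' @rdname networkModel
#' @export
setMethod("stimulusWeights", "NetworkModel", function(object) object@H)

#' @rdname networkModel
#' @export
setGeneric("biases", function(object) standardGeneric("biases"))
#' @rdname networkModel
#' @export
setMethod("biases", "NetworkModel", function(object) object@biases)

#' @rdname networkModel
#' @export
setGeneric("kappaParam", function(object) standardGeneric("kappaParam"))
#' @rdname networkModel
#' @export
setMethod("kappaParam", "NetworkModel", function(object) object@kappa)

#' @rdname networkModel
#' @export
setMethod("nNeurons", "NetworkModel", function(object) length(object@biases))
#' @rdname networkModel
#' @export
setMethod("nStimuli", "NetworkModel", function(object) nrow(object@H))

setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel: %d neurons, %d stimuli, kappa = %g\n",
              nNeurons(object), nStimuli(object), object@kappa))
  cat(sprintf("  %d neuron->neuron edges, %d stimulus->neuron edges\n",
              sum(object@W != 0), sum(object@H != 0)))
})

#' Ground-truth network from the simulators
#'
#' A \linkS4class{NetworkModel} augmented with the cluster assignment and
#' the generation parameters, so that simulated recoveries can be scored
#' against it.
#'
#' @slot clusters integer cluster id per neuron.
#' @slot params list of generation parameters (densities, weight
#'   distributions, inhibitory fraction, seed).
#' @export
setClass("GroundTruthNetwork", contains = "NetworkModel",
         representation(clusters = "integer", params = "list"))

setMethod("show", "GroundTruthNetwork", function(object) {
  callNextMethod()
  cat(sprintf("  %d cluster(s); %d inhibitory inter-neuron edges\n",
              length(unique(object@clusters)), sum(object@W < 0)))
})

#' Result of elastic-forward regressor selection for one neuron
#'
#' @slot parentSet selected regressor labels.
#' @slot fit full-data \linkS4class{NeuronFit} of the selected set.
#' @slot history per-step acceptance record.
#' @slot config the \code{selectionConfig} list used.
#' @export
setClass("SelectionResult",
         representation(parentSet = "character", fit = "NeuronFit",
                        history = "data.frame", config = "list"))

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: parents {%s}, BIC %.3f\n",
              paste(object@parentSet, collapse = ", "), object@fit@bic))
})

#' Per-stimulus active-learning score table
#'
#' Deviance-weighted expected-rate-change scores per stimulus, their
#' z-scores across stimuli, the truncated z-scores, and the resulting
#' stimulus probability distribution.
#'
#' @slot ercNeuron stimuli x neurons expected rate-change ratios.
#' @slot ercStim stimuli x stimuli closed-form rate-change ratios.
#' @slot devianceNeuron neurons x neurons candidate-edge deviances
#'   (source x target; NA where the edge is already in the model).
#' @slot devianceStim stimuli x neurons candidate-edge deviances.
#' @slot scW,scH,scTotal per-stimulus scores (W part, H part, total).
#' @slot z,zClipped per-stimulus z-scores before/after truncation.
#' @slot probs emitted stimulus probability distribution.
#' @export
setClass("StimulusScoreTable",
         representation(ercNeuron = "matrix", ercStim = "matrix",
                        devianceNeuron = "matrix", devianceStim = "matrix",
                        scW = "numeric", scH = "numeric", scTotal = "numeric",
                        z = "numeric", zClipped = "numeric", probs = "numeric"))

setValidity("StimulusScoreTable", function(object) {
  if (any(object@probs < 0)) return("probabilities must be non-negative")
  TRUE
})

setMethod("show", "StimulusScoreTable", function(object) {
  cat(sprintf("StimulusScoreTable: %d stimuli; top stimulus %d (p = %.3f)\n",
              length(object@probs), which.max(object@probs), max(object@probs)))
})

#' @rdname stimulusScores
#' @param object a \code{StimulusScoreTable}.
#' @export
setGeneric("stimulusProbabilities", function(object) standardGeneric("stimulusProbabilities"))
#' @rdname stimulusScores
#' @export
setMethod("stimulusProbabilities", "StimulusScoreTable", function(object) object@probs)
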