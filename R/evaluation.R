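## Recovery metrics against ground truth, held-out likelihood comparison,
## and long-range (rate-propagated) forecasting.

#' Edge-recovery precision, recall and F1
#'
#' Presence-only comparison of estimated and true parent sets, with
#' set-intersection counts summed over neurons:
#' precision = sum |est \eqn{\cap} true| / sum |est|,
#' recall = sum |est \eqn{\cap} true| / sum |true|,
#' F1 = 2 p r / (p + r).  Signs and weights are ignored.  Every 0/0 is
#' defined as 0.  Reported for the inter-neuron matrix W only, the
#' stimulus matrix H only, and combined.
#'
#' @param estimated a \linkS4class{NetworkModel}.
#' @param truth a \linkS4class{NetworkModel} (typically
#'   \linkS4class{GroundTruthNetwork}) of the same dimensions.
#' @return list of named vectors \code{combined}, \code{W}, \code{H},
#'   each with precision, recall, f1.
#' @export
edgeRecoveryMetrics <- function(estimated, truth) {
  stopifnot(nNeurons(estimated) == nNeurons(truth),
            nStimuli(estimated) == nStimuli(truth))
  prf <- function(est, tru) {
    tp <- sum(est & tru)
    p <- if (sum(est) > 0) tp / sum(est) else 0
    r <- if (sum(tru) > 0) tp / sum(tru) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f1)
  }
  eW <- estimated@W != 0; tW <- truth@W != 0
  eH <- estimated@H != 0; tH <- truth@H != 0
  list(combined = prf(rbind(eW, eH), rbind(tW, tH)),
       W = prf(eW, tW), H = prf(eH, tH))
}

#' Misclassified-edge matrices
#'
#' Symmetric difference (XOR) of estimated and true presence, per matrix;
#' empties as the estimate converges to the truth.
#'
#' @inheritParams edgeRecoveryMetrics
#' @return list with logical matrices \code{W} and \code{H}.
#' @export
misclassifiedEdges <- function(estimated, truth) {
  list(W = (estimated@W != 0) != (truth@W != 0),
       H = (estimated@H != 0) != (truth@H != 0))
}

## Per-neuron log-likelihood of observed data under a NetworkModel's
## parameters (observed regressor histories).
modelLogLik <- function(model, experiment) {
  design <- buildRegressors(experiment, model@spikeWindow, model@stimWindow)
  rows <- seq.int(design@validFrom, nrow(design@matrix))
  neurons <- design@labels[design@types == "neuron"]
  stims <- design@labels[design@types == "stimulus"]
  X <- design@matrix[rows, neurons, drop = FALSE]
  S <- design@matrix[rows, stims, drop = FALSE]
  eta <- sweep(X %*% model@W + S %*% model@H, 2, model@biases, "+")
  counts <- spikeCounts(experiment)[rows, , drop = FALSE]
  vapply(seq_len(nNeurons(model)), function(c)
    sum(counts[, c] * logNonlinearity(eta[, c], model@kappa) -
          nonlinearity(eta[, c], model@kappa)), numeric(1))
}

#' Held-out log-likelihood difference between two models
#'
#' Evaluates both models' log-likelihoods per neuron on held-out data
#' (using the observed regressor histories) and returns full minus
#' restricted.  The canonical use compares the full model against the
#' autoregressive (self + stimulus only) model.
#'
#' @param modelFull,modelRestricted \linkS4class{NetworkModel}s sharing
#'   kappa and windows.
#' @param testExperiment held-out \linkS4class{SpikeExperiment}.
#' @return Per-neuron log-likelihood difference.
#' @export
heldoutLogLikDiff <- function(modelFull, modelRestricted, testExperiment) {
  stopifnot(modelFull@kappa == modelRestricted@kappa)
  modelLogLik(modelFull, testExperiment) -
    modelLogLik(modelRestricted, testExperiment)
}

#' Long-range rate forecast
#'
#' Deterministically propagates expected rates through the network: the
#' linear predictor at time t is built from the boxcar sums of PAST
#' EXPECTED RATES (not sampled spikes) plus the observed stimulus
#' history.  The first bins without full history are seeded with each
#' neuron's baseline rate \code{lambda(b_c)}.  Repeated calls are
#' identical.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param stimulusSequence binary bins x stimuli matrix.
#' @return bins x neurons matrix of expected rates.
#' @export
longRangeForecast <- function(model, stimulusSequence) {
  stim <- as.matrix(stimulusSequence)
  m <- nrow(stim)
  nc <- nNeurons(model)
  sw <- model@spikeWindow; tw <- model@stimWindow
  ihat <- boxcarConvolve(stim, tw)
  lam <- matrix(rep(nonlinearity(model@biases, model@kappa), each = m),
                m, nc)
  for (t in seq.int(sw@lower + 1L, m)) {
    xhat <- colSums(lam[(t - sw@lower):(t - sw@upper), , drop = FALSE])
    eta <- model@biases + drop(crossprod(model@W, xhat)) +
      drop(crossprod(model@H, ihat[t, ]))
    lam[t, ] <- nonlinearity(eta, model@kappa)
  }
  colnames(lam) <- colnames(model@W)
  lam
}

#' Log-likelihood of observed spikes under forecast rates
#'
#' @param rates bins x neurons forecast rate matrix.
#' @param spikes bins x neurons observed counts.
#' @param validFrom first row to include (skip the seeded history).
#' @return Per-neuron log-likelihood (constant term dropped).
#' @export
forecastLogLik <- function(rates, spikes, validFrom = 1L) {
  rows <- seq.int(validFrom, nrow(rates))
  vapply(seq_len(ncol(rates)), function(c)
    sum(spikes[rows, c] * log(rates[rows, c]) - rates[rows, c]),
    numeric(1))
}

#' Restrict a model to self-regression and stimulus edges
#'
#' The autoregressive (AR) baseline: off-diagonal inter-neuron weights
#' are zeroed; the diagonal of W and all of H are kept.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @return The restricted \linkS4class{NetworkModel}.
#' @export
toARModel <- function(model) {
  W <- model@W
  W[row(W) != col(W)] <- 0
  networkModel(W, model@H, model@biases, model@kappa,
               model@spikeWindow, model@stimWindow)
}
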