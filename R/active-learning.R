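## Active stimulus selection: deviance-weighted expected-rate-change
## scores per stimulus and the resulting acquisition distribution.

#' Active-learning configuration
#'
#' @param beta smoothing constant in [0, 1]; the surrogate distribution
#'   for stimulus s is \code{(1 - beta) delta_s + beta uniform}
#'   (default 0.25).
#' @param zClip z-score truncation bound (default 2, giving a max/min
#'   probability ratio of at most e^4).
#' @param ercHorizon forward-simulation length (bins) for the neuron
#'   expected-rate-change estimate.
#' @param ercReps Monte-Carlo replicates for that estimate.
#' @param framesPerStimulus consecutive bins per stimulus draw.
#' @param seed RNG seed for the rate-change simulations.
#' @return list of class \code{activeLearningConfig}.
#' @export
activeLearningConfig <- function(beta = 0.25, zClip = 2,
                                 ercHorizon = 2000L, ercReps = 5L,
                                 framesPerStimulus = 4L, seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, zClip > 0, ercHorizon > 10,
            ercReps >= 1, framesPerStimulus >= 1)
  structure(list(beta = beta, zClip = zClip,
                 ercHorizon = as.integer(ercHorizon),
                 ercReps = as.integer(ercReps),
                 framesPerStimulus = as.integer(framesPerStimulus),
                 seed = as.integer(seed)),
            class = "activeLearningConfig")
}

#' Surrogate stimulus distribution favouring one stimulus
#'
#' \code{p_j = (1 - beta) delta(s - j) + beta / nStimuli}: probability
#' mass \code{(1 - beta) + beta / nStimuli} on the favoured stimulus and
#' \code{beta / nStimuli} elsewhere; always sums to one.
#'
#' @param s favoured stimulus index.
#' @param nStimuli number of stimuli.
#' @param beta smoothing constant.
#' @return Probability vector of length \code{nStimuli}.
#' @export
surrogateDistribution <- function(s, nStimuli, beta = 0.25) {
  stopifnot(s >= 1, s <= nStimuli, beta >= 0, beta <= 1)
  p <- rep(beta / nStimuli, nStimuli)
  p[s] <- p[s] + (1 - beta)
  p
}

#' Closed-form expected rate change of a stimulus on a stimulus
#'
#' The ratio of the surrogate probability of stimulus \code{si} under the
#' distribution favouring \code{s} to its uniform probability:
#' \code{(1 - beta) nStimuli delta(s - si) + beta}.  Exact; no simulation
#' is involved for stimulus sources.
#'
#' @inheritParams surrogateDistribution
#' @param si the source stimulus whose rate change is measured.
#' @return Scalar ratio.
#' @export
ercStimulus <- function(s, si, nStimuli, beta = 0.25) {
  (1 - beta) * nStimuli * (s == si) + beta
}

#' @rdname ercStimulus
#' @details \code{ercStimulusMatrix} returns the full
#'   \code{nStimuli x nStimuli} matrix (favoured stimulus by source
#'   stimulus).
#' @export
ercStimulusMatrix <- function(nStimuli, beta = 0.25) {
  outer(seq_len(nStimuli), seq_len(nStimuli),
        function(s, si) ercStimulus(s, si, nStimuli, beta))
}

#' Expected rate change of each stimulus on each neuron
#'
#' Estimates, for every stimulus s and neuron c, the ratio of c's
#' expected rate under stimulation drawn from the surrogate distribution
#' favouring s to its expected rate under uniform stimulation, by seeded
#' forward simulation of the fitted network.  Common random numbers (the
#' same uniforms drive the stimulus draws and the Poisson inversions in
#' both conditions) cancel most Monte-Carlo noise from the ratio.  A
#' neuron with zero denominator rate gets ratio 1 (uninformative).
#'
#' @param model a fitted \linkS4class{NetworkModel}.
#' @param config an \code{\link{activeLearningConfig}}.
#' @return \code{nStimuli x nNeurons} matrix of rate ratios.
#' @export
ercNeuron <- function(model, config = activeLearningConfig()) {
  ns <- nStimuli(model)
  nc <- nNeurons(model)
  m <- config$ercHorizon
  nDraws <- ceiling(m / config$framesPerStimulus)
  num <- matrix(0, ns, nc)
  den <- rep(0, nc)
  for (rep in seq_len(config$ercReps)) {
    uStim <- withSeed(subSeed(config$seed, 17L, rep), runif(nDraws))
    uSpk <- withSeed(subSeed(config$seed, 23L, rep),
                     matrix(runif(m * nc), m, nc))
    stimU <- stimulusSequenceFromUniform(uStim, ns, m, NULL,
                                         config$framesPerStimulus)
    base <- simulatePoissonNetwork(model, stimU, uniforms = uSpk)
    den <- den + attr(base, "rateMean")
    for (s in seq_len(ns)) {
      probs <- surrogateDistribution(s, ns, config$beta)
      stimS <- stimulusSequenceFromUniform(uStim, ns, m, probs,
                                           config$framesPerStimulus)
      sur <- simulatePoissonNetwork(model, stimS, uniforms = uSpk)
      num[s, ] <- num[s, ] + attr(sur, "rateMean")
    }
  }
  ratio <- sweep(num, 2, den, "/")
  ratio[, den <= 0] <- 1
  dimnames(ratio) <- list(rownames(model@H), colnames(model@W))
  ratio
}

#' Deviance of every candidate (absent) edge
#'
#' For every source (neuron or stimulus) and target neuron whose edge is
#' not in the current model, refits the target's MLE with the source
#' added (warm-started from the current estimate) and records twice the
#' log-likelihood gain.  Values are clamped non-negative (the likelihood
#' cannot decrease when a regressor is added at the MLE); a refit that
#' fails to converge contributes 0.  Entries for edges already in the
#' model are NA.
#'
#' @param experiment the \linkS4class{SpikeExperiment} observed so far.
#' @param design its \linkS4class{RegressorDesign}.
#' @param selections per-neuron \linkS4class{SelectionResult} list.
#' @param kappa nonlinearity constant.
#' @return list with \code{neuron} (neurons x neurons, source x target)
#'   and \code{stimulus} (stimuli x neurons) deviance matrices.
#' @export
devianceCandidates <- function(experiment, design, selections, kappa = 10) {
  counts <- spikeCounts(experiment)
  neurons <- design@labels[design@types == "neuron"]
  stims <- design@labels[design@types == "stimulus"]
  devN <- matrix(NA_real_, length(neurons), length(neurons),
                 dimnames = list(neurons, neurons))
  devS <- matrix(NA_real_, length(stims), length(neurons),
                 dimnames = list(stims, neurons))
  for (ci in seq_along(neurons)) {
    fit <- selections[[ci]]@fit
    pa <- selections[[ci]]@parentSet
    y <- counts[, ci]
    for (src in c(neurons, stims)) {
      if (src %in% pa) next
      d <- tryCatch({
        f2 <- evaluateRegressors(y, design, c(pa, src), kappa,
                                 init = fit@theta)
        if (!f2@converged) 0 else max(0, 2 * (f2@logLik - fit@logLik))
      }, error = function(e) 0)
      if (src %in% neurons) devN[src, ci] <- d else devS[src, ci] <- d
    }
  }
  list(neuron = devN, stimulus = devS)
}

#' Score every stimulus and emit the acquisition distribution
#'
#' The W-part score of stimulus s sums, over source neurons c, the
#' expected rate change of s on c times the mean deviance of c's absent
#' outgoing edges; the H-part does the same over source stimuli with the
#' closed-form stimulus rate change.  Scores are z-scored across stimuli,
#' truncated to \code{[-zClip, zClip]}, and softmaxed into the stimulus
#' distribution for the next batch.  A source with no absent outgoing
#' edges contributes 0 (empty mean); if all scores are equal (zero
#' standard deviation) the distribution is uniform.
#'
#' @param ercNeuronMat stimuli x neurons rate-change matrix
#'   (\code{\link{ercNeuron}}).
#' @param ercStimMat stimuli x stimuli rate-change matrix
#'   (\code{\link{ercStimulusMatrix}}).
#' @param deviances candidate-edge deviances
#'   (\code{\link{devianceCandidates}}).
#' @param zClip truncation bound.
#' @return A \linkS4class{StimulusScoreTable}.
#' @export
stimulusScores <- function(ercNeuronMat, ercStimMat, deviances, zClip = 2) {
  devN <- deviances$neuron
  devS <- deviances$stimulus
  ns <- nrow(ercNeuronMat)
  stopifnot(ncol(ercNeuronMat) == nrow(devN), nrow(devS) == ns,
            nrow(ercStimMat) == ns, ncol(ercStimMat) == ns)
  meanDevN <- apply(devN, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else mean(x)
  })
  meanDevS <- apply(devS, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else mean(x)
  })
  scW <- drop(ercNeuronMat %*% meanDevN)
  scH <- drop(ercStimMat %*% meanDevS)
  scTotal <- scW + scH
  dist <- scoresToDistribution(scTotal, zClip)
  new("StimulusScoreTable", ercNeuron = ercNeuronMat, ercStim = ercStimMat,
      devianceNeuron = devN, devianceStim = devS,
      scW = scW, scH = scH, scTotal = scTotal,
      z = attr(dist, "z"), zClipped = attr(dist, "zClipped"),
      probs = as.numeric(dist))
}

#' Scores to stimulus probability distribution
#'
#' Z-scores the per-stimulus scores, truncates to \code{[-zClip, zClip]}
#' and applies the softmax.  Equal scores (zero standard deviation) give
#' the uniform distribution.  The truncation bounds the ratio between any
#' two probabilities by \code{exp(2 zClip)}.
#'
#' @param scores per-stimulus score vector (length >= 2).
#' @param zClip truncation bound (default 2).
#' @return Probability vector with attributes \code{"z"} and
#'   \code{"zClipped"}.
#' @export
scoresToDistribution <- function(scores, zClip = 2) {
  ns <- length(scores)
  stopifnot(ns >= 2)
  s <- sd(scores)
  z <- if (!is.finite(s) || s == 0) rep(0, ns) else (scores - mean(scores)) / s
  zc <- pmax(pmin(z, zClip), -zClip)
  e <- exp(zc - max(zc))
  p <- e / sum(e)
  attr(p, "z") <- z
  attr(p, "zClipped") <- zc
  p
}

#' A simulator-backed sample source for the active loop
#'
#' Wraps a ground-truth network as the acquisition device: each call
#' draws a stimulus sequence from the requested distribution, simulates
#' the network's Poisson response, and returns the new rows.
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param framesPerStimulus consecutive bins per stimulus draw.
#' @param seed base seed; each acquisition folds in a call counter.
#' @param lif optional \code{\link{lifConfig}}: when supplied, spiking is
#'   simulated with the LIF dynamics instead of the Poisson GLM.
#' @return function(probs, nBins) returning a
#'   \linkS4class{SpikeExperiment}.
#' @export
simulatorSource <- function(truth, framesPerStimulus = 4L, seed = 1L,
                            lif = NULL) {
  calls <- 0L
  function(probs, nBins) {
    calls <<- calls + 1L
    stim <- generateStimulusSequence(nStimuli(truth), nBins, probs,
                                     framesPerStimulus,
                                     seed = subSeed(seed, 101L, calls))
    if (is.null(lif))
      simulatePoissonNetwork(truth, stim, seed = subSeed(seed, 103L, calls))
    else
      simulateLIFNetwork(truth, lif, stim, seed = subSeed(seed, 103L, calls))
  }
}

#' Run the closed-loop active-learning experiment
#'
#' Iterates: full elastic-forward re-selection for every neuron, the
#' candidate-edge deviance table, per-stimulus scores, the softmaxed
#' stimulus distribution, and acquisition of the next batch from the
#' sample source.  With \code{beta = 1} every emitted distribution is
#' exactly uniform, reproducing random stimulation.
#'
#' @param source a sample source: function(probs, nBins) returning a
#'   \linkS4class{SpikeExperiment} (see \code{\link{simulatorSource}}).
#' @param initial the initial \linkS4class{SpikeExperiment}.
#' @param nInterventions number of acquisition rounds.
#' @param batchSize bins acquired per round.
#' @param selConfig a \code{\link{selectionConfig}}.
#' @param alConfig an \code{\link{activeLearningConfig}}.
#' @param kappa nonlinearity constant.
#' @param spikeWindow,stimWindow boxcar windows.
#' @param truth optional \linkS4class{GroundTruthNetwork}; when given,
#'   per-intervention precision/recall/F1 are recorded.
#' @param finalFit if TRUE (default), refit after the last acquisition.
#' @return list of class \code{activeLoopTrace}: per-intervention entries
#'   (model, probs, sample count, metrics) plus \code{final}.
#' @export
runActiveLoop <- function(source, initial, nInterventions, batchSize,
                          selConfig = selectionConfig(),
                          alConfig = activeLearningConfig(),
                          kappa = 10,
                          spikeWindow = boxcarWindow(5, 2),
                          stimWindow = boxcarWindow(5, 2),
                          truth = NULL, finalFit = TRUE) {
  experiment <- initial
  trace <- vector("list", nInterventions)
  for (l in seq_len(nInterventions)) {
    design <- buildRegressors(experiment, spikeWindow, stimWindow)
    fit <- fitNetwork(experiment, selConfig, kappa, design = design)
    cfgL <- alConfig
    cfgL$seed <- subSeed(alConfig$seed, 41L, l)
    if (cfgL$beta >= 1) {
      # degenerate smoothing: every surrogate equals the uniform
      # distribution, all rate-change ratios are 1 and all scores tie, so
      # the loop reduces exactly to uniform (random) stimulation
      scores <- NULL
      probs <- rep(1 / nStimuli(fit$model), nStimuli(fit$model))
    } else {
      dev <- devianceCandidates(experiment, design, fit$selections, kappa)
      ercN <- ercNeuron(fit$model, cfgL)
      ercS <- ercStimulusMatrix(nStimuli(fit$model), cfgL$beta)
      scores <- stimulusScores(ercN, ercS, dev, cfgL$zClip)
      probs <- stimulusProbabilities(scores)
    }
    metrics <- if (!is.null(truth)) edgeRecoveryMetrics(fit$model, truth)
    trace[[l]] <- list(intervention = l, samples = nBins(experiment),
                       model = fit$model, scores = scores, probs = probs,
                       metrics = metrics)
    batch <- tryCatch(source(probs, batchSize), error = function(e) {
      warning("sample source failed at intervention ", l, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(batch)) {
      trace <- trace[seq_len(l)]
      break
    }
    experiment <- appendSamples(experiment, batch)
  }
  out <- list(interventions = trace, experiment = experiment)
  if (finalFit) {
    fit <- fitNetwork(experiment, selConfig, kappa,
                      spikeWindow = spikeWindow, stimWindow = stimWindow)
    out$final <- list(samples = nBins(experiment), model = fit$model,
                      metrics = if (!is.null(truth))
                        edgeRecoveryMetrics(fit$model, truth))
  }
  class(out) <- "activeLoopTrace"
  out
}
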