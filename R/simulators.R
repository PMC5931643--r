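## Ground-truth generators and spiking simulators: small-world directed
## networks, Poisson-GLM dynamics, leaky integrate-and-fire dynamics,
## stimulus sequence generation, and Hartley stimulus encoding.

#' Generate a small-world ground-truth network
#'
#' Builds one directed Watts-Strogatz-style ring per cluster: a
#' nearest-neighbour directed ring is thinned or thickened to hit the
#' target directed edge density exactly, then each edge is rewired to a
#' random target with probability \code{rewireProb} (short-range wiring
#' plus a few long-range shortcuts).  Inter-neuron rate increments are
#' drawn from per-cluster normal distributions and converted to weights
#' that produce exactly that conditional rate change at the network's
#' nonlinearity when the parent's boxcar sum is 1; an exact (rounded)
#' fraction of inter-neuron edges is negated (inhibitory).  Only a
#' fraction of stimuli receive outgoing (always excitatory) edges - the
#' rest are confounders with no effect on the network.
#'
#' @param nClusters number of independent clusters.
#' @param neuronsPerCluster neurons per cluster.
#' @param density target directed edge density over ordered within-cluster
#'   neuron pairs (0 < density < 1).
#' @param weightMeanPerCluster per-cluster mean rate increment (recycled).
#' @param weightSd rate-increment standard deviation.
#' @param inhibitoryFraction fraction of inter-neuron edges negated;
#'   enforced exactly as \code{round(fraction * nEdges)}.
#' @param nStimuli number of stimuli (wired plus confounders).
#' @param stimWeightMean,stimWeightSd stimulus rate-increment distribution.
#' @param activeStimFraction fraction of stimuli that get outgoing edges.
#' @param stimTargets neurons wired per active stimulus.
#' @param baseRate baseline spiking rate per bin (sets all biases).
#' @param kappa nonlinearity constant.
#' @param rewireProb per-edge rewiring probability.
#' @param spikeWindow,stimWindow boxcar windows carried by the model.
#' @param seed RNG seed; generation is fully reproducible per seed.
#' @return A \linkS4class{GroundTruthNetwork}.
#' @export
makeSmallWorldNetwork <- function(nClusters = 1L, neuronsPerCluster = 18L,
                                  density = 0.03,
                                  weightMeanPerCluster = 0.05,
                                  weightSd = 0.005,
                                  inhibitoryFraction = 0.3,
                                  nStimuli = 30L,
                                  stimWeightMean = 0.10,
                                  stimWeightSd = 0.014,
                                  activeStimFraction = 1 / 6,
                                  stimTargets = 3L,
                                  baseRate = 0.05, kappa = 10,
                                  rewireProb = 0.1,
                                  spikeWindow = boxcarWindow(5, 2),
                                  stimWindow = boxcarWindow(5, 2),
                                  seed = 1L) {
  stopifnot(density > 0, density < 1, inhibitoryFraction >= 0,
            inhibitoryFraction <= 1, activeStimFraction >= 0,
            activeStimFraction <= 1, baseRate > 0)
  nc <- nClusters * neuronsPerCluster
  means <- rep_len(weightMeanPerCluster, nClusters)
  clusters <- rep(seq_len(nClusters), each = neuronsPerCluster)
  b <- nonlinearityInverse(baseRate, kappa)
  withSeed(seed, {
    W <- matrix(0, nc, nc)
    edges <- NULL
    for (cl in seq_len(nClusters)) {
      offset <- (cl - 1L) * neuronsPerCluster
      e <- ringLatticeEdges(neuronsPerCluster, density, rewireProb)
      if (nrow(e)) edges <- rbind(edges, cbind(e + offset, cl))
    }
    inc <- rnorm(nrow(edges), mean = means[edges[, 3]], sd = weightSd)
    inc <- pmax(inc, 1e-4)
    w <- rateIncrementToWeight(inc, baseRate, kappa)
    nInhib <- round(inhibitoryFraction * nrow(edges))
    if (nInhib > 0) {
      inhib <- sample(nrow(edges), nInhib)
      w[inhib] <- -w[inhib]
    }
    W[edges[, 1:2, drop = FALSE]] <- w

    H <- matrix(0, nStimuli, nc)
    nActive <- round(activeStimFraction * nStimuli)
    if (nActive > 0) {
      active <- sort(sample(nStimuli, nActive))
      for (s in active) {
        targets <- sample(nc, min(stimTargets, nc))
        incS <- pmax(rnorm(length(targets), stimWeightMean, stimWeightSd), 1e-4)
        H[s, targets] <- rateIncrementToWeight(incS, baseRate, kappa)
      }
    }
    dimnames(W) <- list(paste0("n", 1:nc), paste0("n", 1:nc))
    dimnames(H) <- list(paste0("s", seq_len(nStimuli)), paste0("n", 1:nc))
    new("GroundTruthNetwork", W = W, H = H, biases = rep(b, nc),
        kappa = kappa, spikeWindow = spikeWindow, stimWindow = stimWindow,
        clusters = as.integer(clusters),
        params = list(nClusters = nClusters,
                      neuronsPerCluster = neuronsPerCluster,
                      density = density,
                      weightMeanPerCluster = means, weightSd = weightSd,
                      inhibitoryFraction = inhibitoryFraction,
                      nStimuli = nStimuli, stimWeightMean = stimWeightMean,
                      stimWeightSd = stimWeightSd,
                      activeStimFraction = activeStimFraction,
                      stimTargets = stimTargets, baseRate = baseRate,
                      rewireProb = rewireProb, seed = seed))
  })
}

## Directed ring lattice at an exact target edge count, Watts-Strogatz
## rewired.  Errors when the density is infeasible for the node count.
ringLatticeEdges <- function(n, density, rewireProb) {
  target <- round(density * n * (n - 1))
  if (target > n * (n - 1))
    stop("edge density ", density, " infeasible for ", n, " nodes")
  if (target == 0) return(matrix(integer(0), 0, 2))
  edges <- NULL
  hop <- 1L
  while (is.null(edges) || nrow(edges) < target) {
    ring <- cbind(1:n, (0:(n - 1) + hop) %% n + 1L)
    edges <- rbind(edges, ring)
    hop <- hop + 1L
    if (hop > n - 1L) break
  }
  edges <- edges[sample(nrow(edges), target), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    if (runif(1) < rewireProb) {
      src <- edges[i, 1]
      used <- edges[edges[, 1] == src, 2]
      free <- setdiff(seq_len(n), c(src, used))
      if (length(free)) edges[i, 2] <- free[sample.int(length(free), 1)]
    }
  }
  unique(edges)
}

#' Convert a conditional rate increment to an edge weight
#'
#' The weight w such that \code{lambda(b + w) - lambda(b) = increment}
#' when the parent's boxcar sum equals one, i.e. a single parent event in
#' the influence window raises the child's rate by exactly
#' \code{increment}.
#'
#' @param increment desired rate change (positive).
#' @param baseRate child's baseline rate \code{lambda(b)}.
#' @param kappa nonlinearity constant.
#' @return Weight(s) on the linear-predictor scale.
#' @export
rateIncrementToWeight <- function(increment, baseRate, kappa = 10) {
  nonlinearityInverse(baseRate + increment, kappa) -
    nonlinearityInverse(baseRate, kappa)
}

#' Preset ground-truth networks
#'
#' \code{"sw1cl"}: one 18-neuron small-world cluster with rate increments
#' N(0.05, 0.005) and 30 stimuli (increments N(0.10, 0.014)), 30\% of
#' inter-neuron edges inhibitory.  \code{"sw3cl"}: three 18-neuron
#' clusters with per-cluster increment means 0.075 / 0.05 / 0.035.  Both
#' use directed density 0.03, kappa 10, baseline rate 0.05/bin and boxcar
#' windows t-5 ... t-2.
#'
#' @param preset "sw1cl" or "sw3cl".
#' @param seed RNG seed.
#' @return A \linkS4class{GroundTruthNetwork}.
#' @export
swPreset <- function(preset = c("sw1cl", "sw3cl"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "sw1cl") {
    makeSmallWorldNetwork(nClusters = 1L, neuronsPerCluster = 18L,
                          weightMeanPerCluster = 0.05, stimTargets = 3L,
                          seed = seed)
  } else {
    makeSmallWorldNetwork(nClusters = 3L, neuronsPerCluster = 18L,
                          weightMeanPerCluster = c(0.075, 0.05, 0.035),
                          stimTargets = 6L, seed = seed)
  }
}

#' Candidate regressor count of a design
#'
#' Each neuron has \code{nNeurons + nStimuli} candidate regressors
#' (self-edges included, bias excluded); the network total multiplies by
#' the number of neurons.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @return list with \code{perNeuron} and \code{total}.
#' @export
candidateCount <- function(model) {
  per <- nNeurons(model) + nStimuli(model)
  list(perNeuron = per, total = per * nNeurons(model))
}

#' Generate a stimulus indicator sequence
#'
#' Stimuli are drawn i.i.d. from \code{probs} and each draw is held for
#' \code{framesPerStimulus} consecutive bins (one-hot rows; the last block
#' may be truncated at \code{nBins}).
#'
#' @param nStimuli number of stimuli.
#' @param nBins sequence length in bins.
#' @param probs stimulus distribution (default uniform).
#' @param framesPerStimulus consecutive bins per draw (default 4).
#' @param seed RNG seed.
#' @return Binary \code{nBins x nStimuli} matrix with columns s1, s2, ...
#' @export
generateStimulusSequence <- function(nStimuli, nBins, probs = NULL,
                                     framesPerStimulus = 4L, seed = 1L) {
  stopifnot(framesPerStimulus >= 1)
  nDraws <- ceiling(nBins / framesPerStimulus)
  u <- withSeed(seed, runif(nDraws))
  stimulusSequenceFromUniform(u, nStimuli, nBins, probs, framesPerStimulus)
}

## Deterministic sequence construction from supplied uniforms (shared
## uniforms give coupled sequences across different distributions).
stimulusSequenceFromUniform <- function(u, nStimuli, nBins, probs = NULL,
                                        framesPerStimulus = 4L) {
  if (is.null(probs)) probs <- rep(1 / nStimuli, nStimuli)
  stopifnot(length(probs) == nStimuli, all(probs >= 0), sum(probs) > 0)
  idx <- categoricalFromUniform(u, probs)
  seqIdx <- rep(idx, each = framesPerStimulus)[seq_len(nBins)]
  out <- matrix(0, nBins, nStimuli,
                dimnames = list(NULL, paste0("s", seq_len(nStimuli))))
  out[cbind(seq_len(nBins), seqIdx)] <- 1
  out
}

#' Simulate spiking from a Poisson GLM network
#'
#' Iterates bin by bin: the linear predictor of each neuron is built from
#' the boxcar history of all spikes and stimuli, passed through the
#' softplus-kappa nonlinearity, and counts are drawn from the resulting
#' Poisson rate.  Early bins use the partially available history.
#' Identical seeds give identical spike matrices.
#'
#' @param truth a \linkS4class{NetworkModel} (typically a
#'   \linkS4class{GroundTruthNetwork}).
#' @param stimulusSequence binary bins x stimuli matrix.
#' @param seed RNG seed.
#' @param uniforms optional bins x neurons uniforms (overrides
#'   \code{seed}; used for common-random-number coupling).
#' @return A \linkS4class{SpikeExperiment} with attribute
#'   \code{"rateMean"} (per-neuron mean simulated rate).
#' @export
simulatePoissonNetwork <- function(truth, stimulusSequence, seed = 1L,
                                   uniforms = NULL) {
  stim <- as.matrix(stimulusSequence)
  m <- nrow(stim)
  nc <- nNeurons(truth)
  stopifnot(ncol(stim) == nStimuli(truth),
            truth@spikeWindow@lower < m)
  if (is.null(uniforms))
    uniforms <- withSeed(seed, matrix(runif(m * nc), m, nc))
  res <- cpp_simulate_poisson(truth@W, truth@H, truth@biases, truth@kappa,
                              stim, truth@spikeWindow@lower,
                              truth@spikeWindow@upper, uniforms)
  counts <- res$counts
  colnames(counts) <- paste0("n", seq_len(nc))
  out <- spikeExperiment(counts, stim)
  attr(out, "rateMean") <- drop(res$rate_mean)
  out
}

#' LIF simulator configuration
#'
#' @param a synaptic density of the alpha-like kernel
#'   \code{h(t) = a^2 exp(-a (t - tD)) (t - tD)} for \code{t >= tD}
#'   (integrates to 1 over its support).
#' @param tD kernel delay in bins.
#' @param bMax direct-current upper bound; each bin draws
#'   \code{b(t) ~ U[0, bMax]}.  \code{NA} calibrates bMax so the baseline
#'   (input-free) spiking probability matches \code{targetRate}.
#' @param targetRate baseline rate used when \code{bMax} is NA.
#' @return list of class \code{lifConfig}.
#' @export
lifConfig <- function(a = 1.5, tD = 2L, bMax = NA_real_, targetRate = 0.05) {
  stopifnot(a > 0, tD >= 0)
  if (is.na(bMax)) bMax <- 1 / (1 - targetRate)
  structure(list(a = a, tD = as.integer(tD), bMax = bMax),
            class = "lifConfig")
}

#' Rescale GLM edge weights for the LIF simulator
#'
#' Linearly rescales W and H so conditional spiking-rate changes are
#' preserved: in the GLM a parent spike adds (window length) x
#' lambda'(eta0) x w expected child spikes; in the LIF (with unit-area
#' kernel and uniform current) it adds w / bMax.  The match gives
#' \code{w_LIF = w_GLM * windowLength * lambda'(eta0) * bMax}.
#'
#' @param truth a \linkS4class{NetworkModel}.
#' @param config a \code{\link{lifConfig}}.
#' @return list with rescaled \code{W} and \code{H}.
#' @export
lifWeightsFromModel <- function(truth, config) {
  eta0 <- mean(truth@biases)
  dlam <- stats::plogis(truth@kappa * eta0)
  f <- windowLength(truth@spikeWindow) * dlam * config$bMax
  list(W = truth@W * f, H = truth@H * f)
}

#' Simulate spiking from a leaky integrate-and-fire network
#'
#' Euler discretization with one step per bin of
#' \code{v' = -v + b(t) + sum W (s * h) + sum H (I * h)}; threshold 1,
#' reset to 0, one spike per crossing.  The synaptic kernel is truncated
#' at \code{10 / a} bins past its delay.  Weights are rescaled from the
#' GLM ground truth via \code{\link{lifWeightsFromModel}}.
#'
#' @param truth a \linkS4class{NetworkModel}.
#' @param config a \code{\link{lifConfig}}.
#' @param stimulusSequence binary bins x stimuli matrix.
#' @param seed RNG seed (drives the uniform direct current).
#' @return A \linkS4class{SpikeExperiment} of 0/1 spikes.
#' @export
simulateLIFNetwork <- function(truth, config, stimulusSequence, seed = 1L) {
  stim <- as.matrix(stimulusSequence)
  m <- nrow(stim)
  nc <- nNeurons(truth)
  wh <- lifWeightsFromModel(truth, config)
  kernelLen <- config$tD + ceiling(10 / config$a)
  bcur <- withSeed(seed, matrix(runif(m * nc, 0, config$bMax), m, nc))
  spikes <- cpp_simulate_lif(wh$W, wh$H, bcur, stim, config$a, config$tD,
                             as.integer(kernelLen))
  colnames(spikes) <- paste0("n", seq_len(nc))
  spikeExperiment(spikes, stim)
}

#' LIF synaptic kernel
#'
#' \code{h(t) = a^2 exp(-a (t - tD)) (t - tD)} for \code{t >= tD}, zero
#' before; integrates to 1 over \code{[tD, Inf)}.
#'
#' @param t time (bins), vectorized.
#' @param a synaptic density.
#' @param tD kernel delay.
#' @return Kernel values.
#' @export
lifKernel <- function(t, a = 1.5, tD = 2) {
  x <- t - tD
  ifelse(x >= 0, a^2 * exp(-a * x) * x, 0)
}

#' Encode a Hartley grating stimulus into an (r, phi) class
#'
#' A Hartley basis stimulus is parameterized by amplitude A = +-1 and
#' integer frequency components kx, ky in \{-maxFreq, ..., maxFreq\}.  To
#' limit data fragmentation the basis is encoded by spatial frequency
#' \code{r = sqrt(kx^2 + ky^2)} and orientation \code{phi = atan2(ky, kx)},
#' each discretized into \code{nLevels} equal-width bins over its
#' attainable range (r over [0, sqrt(2) * maxFreq], phi over (-pi, pi]),
#' yielding \code{nLevels^2} stimulus classes.
#'
#' @param A amplitude, +1 or -1 (does not affect the class).
#' @param kx,ky integer frequency components.
#' @param maxFreq maximum absolute frequency (default 12).
#' @param nLevels discretization levels per coordinate (default 7).
#' @return list with r, phi, rBin, phiBin (0-based) and class
#'   (0 ... nLevels^2 - 1, equal to rBin * nLevels + phiBin).
#' @export
encodeHartley <- function(A, kx, ky, maxFreq = 12L, nLevels = 7L) {
  if (!A %in% c(-1, 1)) stop("A must be +1 or -1")
  if (abs(kx) > maxFreq || abs(ky) > maxFreq || kx != round(kx) || ky != round(ky))
    stop("kx, ky must be integers in [-", maxFreq, ", ", maxFreq, "]")
  r <- sqrt(kx^2 + ky^2)
  phi <- atan2(ky, kx)
  rMax <- sqrt(2) * maxFreq
  rBin <- min(floor(r / rMax * nLevels), nLevels - 1L)
  phiBin <- min(floor((phi + pi) / (2 * pi) * nLevels), nLevels - 1L)
  list(A = A, kx = kx, ky = ky, r = r, phi = phi,
       rBin = as.integer(rBin), phiBin = as.integer(phiBin),
       class = as.integer(rBin * nLevels + phiBin))
}

#' @rdname encodeHartley
#' @details \code{hartleyClassCount} returns the number of distinct
#'   (r, phi) classes, \code{nLevels^2}.
#' @export
hartleyClassCount <- function(nLevels = 7L) as.integer(nLevels^2)
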