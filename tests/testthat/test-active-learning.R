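# Stimulus scoring and the acquisition distribution.

test_that("surrogate distribution follows its closed form and sums to one", {
  expect_equal(surrogateDistribution(3, 30, beta = 1), rep(1 / 30, 30))
  p <- surrogateDistribution(4, 30, beta = 0.25)
  expect_equal(p[4], 0.75 + 0.25 / 30, tolerance = 1e-12)   # 0.7583...
  expect_equal(unname(p[1]), 0.25 / 30, tolerance = 1e-12)  # 0.00833...
  for (beta in c(0, 0.1, 0.5, 0.9)) {
    for (ns in c(2, 7, 30)) {
      expect_equal(sum(surrogateDistribution(1, ns, beta)), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("stimulus-on-stimulus rate change matches the closed form exactly", {
  expect_equal(ercStimulus(5, 5, 30, beta = 0.25), 0.75 * 30 + 0.25)  # 22.75
  expect_equal(ercStimulus(5, 6, 30, beta = 0.25), 0.25)
  expect_true(all(ercStimulusMatrix(12, beta = 1) == 1))
  M <- ercStimulusMatrix(30, beta = 0.25)
  expect_equal(unname(diag(M)), rep(22.75, 30))
  expect_equal(unname(M[1, 2]), 0.25)
  # matrix equals the surrogate-to-uniform probability ratio
  for (s in c(1, 17)) {
    expect_equal(unname(M[s, ]), unname(surrogateDistribution(s, 30, 0.25) * 30),
                 tolerance = 1e-12)
  }
})

test_that("neuron rate-change ratios are one when stimuli cannot matter", {
  cfg <- activeLearningConfig(ercHorizon = 600, ercReps = 2, seed = 5)
  # no edges at all: identical dynamics under any stimulus distribution
  erc <- ercNeuron(nullNetwork(6, 8), cfg)
  expect_equal(dim(erc), c(8, 6))
  expect_true(all(erc == 1))
  # beta = 1: the surrogate IS the uniform distribution
  truth <- twoParentNetwork()
  cfg1 <- activeLearningConfig(beta = 1, ercHorizon = 600, ercReps = 2, seed = 5)
  expect_true(all(ercNeuron(truth, cfg1) == 1))
})

test_that("one-edge rate-change ratio matches the closed-form oracle", {
  # single neuron driven by one stimulus through a 1-bin window with
  # 1-bin presentations: the boxcar term is Bernoulli(p_s), so
  # E[lambda] = p_s lambda(b + w) + (1 - p_s) lambda(b) in closed form
  w <- rateIncrementToWeight(0.3, 0.05)
  H <- matrix(0, 4, 1); H[2, 1] <- w
  model <- networkModel(matrix(0, 1, 1), H, biasFor(0.05),
                        spikeWindow = boxcarWindow(1, 1),
                        stimWindow = boxcarWindow(1, 1))
  cfg <- activeLearningConfig(beta = 0.25, ercHorizon = 6000, ercReps = 4,
                              framesPerStimulus = 1, seed = 9)
  erc <- ercNeuron(model, cfg)
  lamOn <- nonlinearity(biasFor(0.05) + w, 10)
  lamOff <- 0.05
  pSur <- 0.75 + 0.25 / 4
  pUni <- 0.25
  oracle <- (pSur * lamOn + (1 - pSur) * lamOff) /
    (pUni * lamOn + (1 - pUni) * lamOff)
  expect_equal(erc[2, 1], oracle, tolerance = 0.05)
  expect_gt(erc[2, 1], 1)
})

test_that("candidate-edge deviances behave per the likelihood-ratio definition", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 2500, seed = 101)
  d <- buildRegressors(ex)
  fit <- fitNetwork(ex, fastCfg(3))
  dev <- devianceCandidates(ex, d, fit$selections)
  expect_true(all(dev$neuron[!is.na(dev$neuron)] >= 0))
  expect_true(all(dev$stimulus[!is.na(dev$stimulus)] >= 0))
  # a stimulus that never fires adds no information
  neverShown <- which(colSums(stimulusIndicators(ex)) == 0)
  if (length(neverShown)) {
    expect_lt(max(dev$stimulus[neverShown[1], ], na.rm = TRUE), 1e-6)
  }
  # entries for edges already in the model are undefined
  for (c in seq_along(fit$selections)) {
    for (lab in fit$selections[[c]]@parentSet) {
      val <- if (startsWith(lab, "n")) dev$neuron[lab, c] else dev$stimulus[lab, c]
      expect_true(is.na(val))
    }
  }
})

test_that("the deviance of a truly missing parent exceeds the chi-square bar", {
  truth <- twoParentNetwork()
  hits <- logical(3)
  for (r in 1:3) {
    ex <- simulateUniform(truth, 2500, seed = 110 + r)
    d <- buildRegressors(ex)
    y <- spikeCounts(ex)[, 1]
    # model that is missing the true stimulus parent s3
    base <- SpikeNetGLM:::glmFitCore(y, d, "n2", 10)
    with <- SpikeNetGLM:::glmFitCore(y, d, c("n2", "s3"), 10,
                                     init = base$theta)
    hits[r] <- 2 * (with$logLik - base$logLik) > qchisq(0.99, 1)
  }
  expect_true(all(hits))
})

test_that("deviance is invariant to the ordering of the existing parent set", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 2000, seed = 115)
  d <- buildRegressors(ex)
  y <- spikeCounts(ex)[, 1]
  a1 <- SpikeNetGLM:::glmFitCore(y, d, c("n2", "s3"), 10)
  a2 <- SpikeNetGLM:::glmFitCore(y, d, c("s3", "n2"), 10)
  d1 <- SpikeNetGLM:::glmFitCore(y, d, c("n2", "s3", "n7"), 10)$logLik - a1$logLik
  d2 <- SpikeNetGLM:::glmFitCore(y, d, c("s3", "n2", "n7"), 10)$logLik - a2$logLik
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("stimulus scores aggregate deviances per the scoring rule", {
  ns <- 5; nc <- 3
  ercN <- matrix(1, ns, nc)
  ercS <- ercStimulusMatrix(ns, beta = 0.25)
  devN <- matrix(NA_real_, nc, nc)
  devS <- matrix(NA_real_, ns, nc)

  # all-zero deviances give all-zero scores and the uniform distribution
  devN[] <- 0; devS[] <- 0
  tab0 <- stimulusScores(ercN, ercS, list(neuron = devN, stimulus = devS))
  expect_true(all(tab0@scTotal == 0))
  expect_equal(stimulusProbabilities(tab0), rep(1 / ns, ns))

  # one candidate edge from neuron 2 with deviance d and unit rate
  # changes: every stimulus scores exactly d
  devN[] <- NA; devS[] <- NA
  devN[2, 3] <- 4.2
  tab1 <- stimulusScores(ercN, ercS, list(neuron = devN, stimulus = devS))
  expect_equal(unname(tab1@scTotal), rep(4.2, ns))

  # doubling the deviances doubles every score
  devN[2, 3] <- 8.4
  tab2 <- stimulusScores(ercN, ercS, list(neuron = devN, stimulus = devS))
  expect_equal(tab2@scTotal, 2 * tab1@scTotal)

  # a stimulus source with an absent edge is weighted by the exact
  # stimulus-on-stimulus rate change
  devN[2, 3] <- NA
  devS[4, 1] <- 2
  tab3 <- stimulusScores(ercN, ercS, list(neuron = devN, stimulus = devS))
  expect_equal(unname(tab3@scTotal), unname(ercS[, 4] * 2))
  expect_equal(which.max(tab3@scTotal), 4L)
})

test_that("score-to-distribution mapping z-scores, clips and softmaxes", {
  # all equal scores: zero spread maps to the uniform distribution
  expect_equal(as.numeric(scoresToDistribution(rep(3.3, 7))), rep(1 / 7, 7))
  # softmax of a clipped pair at z* = (+2, -2) gives e^2/(e^2 + e^-2);
  # reachable when both tails of a larger score vector clip
  p <- scoresToDistribution(c(1000, rep(0, 8), -1000))
  expect_equal(max(p) / min(p), exp(4), tolerance = 1e-10)
  expect_equal(max(p) / (max(p) + min(p)), 0.9820, tolerance = 1e-3)
  expect_equal(min(p) / (max(p) + min(p)), 0.0180, tolerance = 1e-3)
  # raw z beyond the bound is truncated to it
  z <- attr(scoresToDistribution(c(100, rep(0, 20))), "z")
  zc <- attr(scoresToDistribution(c(100, rep(0, 20))), "zClipped")
  expect_gt(max(z), 2)
  expect_lte(max(zc), 2)
  expect_gte(min(zc), -2)
  # distribution equals the softmax of the clipped z-scores
  expect_equal(as.numeric(p), as.numeric(exp(attr(p, "zClipped")) /
                                           sum(exp(attr(p, "zClipped")))),
               tolerance = 1e-12)
  # max/min probability ratio never exceeds e^4
  set.seed(21)
  for (r in 1:20) {
    pr <- as.numeric(scoresToDistribution(rnorm(15, sd = 10^runif(1, -2, 2))))
    expect_lte(max(pr) / min(pr), exp(4) * (1 + 1e-10))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("the active loop traces interventions and emits valid distributions", {
  truth <- twoParentNetwork()
  src <- simulatorSource(truth, seed = 31)
  init <- src(rep(1 / 30, 30), 400)
  tr <- runActiveLoop(src, init, nInterventions = 2, batchSize = 400,
                      selConfig = fastCfg(5),
                      alConfig = activeLearningConfig(ercHorizon = 400,
                                                      ercReps = 2, seed = 7),
                      truth = truth)
  expect_length(tr$interventions, 2)
  for (iv in tr$interventions) {
    expect_equal(sum(iv$probs), 1, tolerance = 1e-12)
    expect_true(all(iv$probs >= 0))
    expect_true(all(c("precision", "recall", "f1") %in%
                      names(iv$metrics$combined)))
  }
  expect_equal(tr$final$samples, 400 + 2 * 400)
})

test_that("beta = 1 reduces the loop to uniform stimulation", {
  truth <- twoParentNetwork()
  src <- simulatorSource(truth, seed = 33)
  init <- src(rep(1 / 30, 30), 400)
  tr <- runActiveLoop(src, init, nInterventions = 1, batchSize = 400,
                      selConfig = fastCfg(5),
                      alConfig = activeLearningConfig(beta = 1, seed = 7))
  expect_equal(tr$interventions[[1]]$probs, rep(1 / 30, 30))
})
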