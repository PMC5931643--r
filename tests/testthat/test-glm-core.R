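# Likelihood machinery: boxcar regressors, nonlinearity, MLE, observed
# Fisher information, Wald tests, BIC, approximate z-score prescreen.

test_that("boxcar regressor columns follow the window definition", {
  m <- 40L
  spikes <- matrix(0L, m, 1)
  stim <- matrix(0, m, 1)
  spikes[10, 1] <- 1L
  ex <- spikeExperiment(spikes, stim)
  d <- buildRegressors(ex, boxcarWindow(5, 2), boxcarWindow(5, 2))
  col <- d@matrix[, "n1"]
  expect_equal(which(col == 1), 12:15)  # bins t with t-5 <= 10 <= t-2
  expect_true(all(col[-(12:15)] == 0))
  expect_equal(d@validFrom, 6L)

  # all-zero source gives an all-zero column
  expect_true(all(d@matrix[, "s1"] == 0))

  # two spikes at consecutive bins: summed where the windows overlap
  spikes2 <- matrix(0L, m, 1)
  spikes2[c(10, 11), 1] <- 1L
  d2 <- buildRegressors(spikeExperiment(spikes2, stim))
  col2 <- d2@matrix[, "n1"]
  expect_equal(unname(col2[12:16]), c(1, 2, 2, 2, 1))
  expect_true(all(col2[-(12:16)] == 0))

  expect_error(buildRegressors(spikeExperiment(spikes[1:4, , drop = FALSE],
                                               stim[1:4, , drop = FALSE])),
               "window")
})

test_that("softplus-kappa nonlinearity matches closed-form values", {
  expect_equal(nonlinearity(0, 10), log(2) / 10, tolerance = 1e-12)
  expect_equal(nonlinearity(1, 10), 1.00000454, tolerance = 1e-7)
  expect_equal(nonlinearity(-1, 10), 4.5399e-6, tolerance = 1e-4)
  # linear regime and strict monotonicity/positivity
  expect_lt(abs(nonlinearity(5, 10) - 5), 1e-3)
  eta <- seq(-3, 3, by = 0.01)
  lam <- nonlinearity(eta, 10)
  expect_true(all(lam > 0))
  expect_true(all(diff(lam) > 0))
  # inverse round-trips
  expect_equal(nonlinearityInverse(nonlinearity(0.3, 10), 10), 0.3,
               tolerance = 1e-10)
})

test_that("log-likelihood matches direct substitution", {
  m <- 105L
  ex <- spikeExperiment(matrix(0L, m, 1), matrix(0, m, 1))
  d <- buildRegressors(ex)   # 100 valid bins
  b <- nonlinearityInverse(0.1, 10)
  y <- rep(0L, m)
  expect_equal(logLikelihood(y, d, character(0), c(bias = b)), -10,
               tolerance = 1e-10)
  y[50] <- 1L
  expect_equal(logLikelihood(y, d, character(0), c(bias = b)),
               log(0.1) - 10, tolerance = 1e-10)
  expect_error(logLikelihood(y[1:10], d, character(0), c(bias = b)),
               "length")
})

test_that("log-likelihood recomputes consistently when weights change", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 600, seed = 5)
  d <- buildRegressors(ex)
  y <- spikeCounts(ex)[, 1]
  th <- c(n2 = 0.1, s3 = 0.2, bias = -0.05)
  ll2 <- logLikelihood(y, d, c("n2", "s3"), 2 * th)
  rows <- seq.int(d@validFrom, nBins(ex))
  eta <- drop(d@matrix[rows, c("n2", "s3", "bias")] %*% (2 * th))
  manual <- sum(y[rows] * log(nonlinearity(eta, 10)) - nonlinearity(eta, 10))
  expect_equal(ll2, manual, tolerance = 1e-10)
})

test_that("bias-only MLE equals the sample mean rate", {
  set.seed(81)
  m <- 2005L
  y <- rpois(m, 0.08)
  ex <- spikeExperiment(cbind(n1 = y), matrix(0, m, 1))
  d <- buildRegressors(ex)
  fit <- fitNeuronGLM(y, d, character(0))
  expect_true(fit@converged)
  rate <- nonlinearity(coef(fit)[["bias"]], 10)
  expect_equal(rate, mean(y[d@validFrom:m]), tolerance = 1e-6)
})

test_that("MLE recovers simulated weights within 3 standard errors", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 8000, seed = 11)
  d <- buildRegressors(ex)
  y <- spikeCounts(ex)[, 1]
  fit <- fitNeuronGLM(y, d, c("n2", "s3"))
  se <- sqrt(diag(solve(fit@fisher)))
  tru <- c(truth@W[2, 1], truth@H[3, 1], truth@biases[1])
  expect_true(all(abs(coef(fit) - tru) <= 3 * se))
})

test_that("warm starts converge in no more iterations than cold starts", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 2000, seed = 13)
  d <- buildRegressors(ex)
  y <- spikeCounts(ex)[, 1]
  cold <- fitNeuronGLM(y, d, c("n2", "s3"))
  warm <- fitNeuronGLM(y, d, c("n2", "s3"), init = cold@theta)
  expect_true(warm@converged)
  expect_lte(warm@iterations, cold@iterations)
  expect_equal(warm@logLik, cold@logLik, tolerance = 1e-8)
})

test_that("observed Fisher equals the finite-difference Hessian", {
  set.seed(3)
  for (rep in 1:3) {
    truth <- twoParentNetwork()
    ex <- simulateUniform(truth, 400, seed = 20 + rep)
    d <- buildRegressors(ex)
    y <- spikeCounts(ex)[, 1]
    pa <- c("n2", "n5", "s3")
    theta <- setNames(c(rnorm(3, 0, 0.1), biasFor(0.05)), c(pa, "bias"))
    J <- observedFisher(y, d, pa, theta, 10)
    Jfd <- finiteDiffFisher(y, d, pa, theta, 10)
    expect_equal(unname(J), Jfd, tolerance = 1e-4)
    expect_equal(unname(J), unname(t(J)))
  }
})

test_that("zero regressor columns produce zero Fisher rows and columns", {
  m <- 300L
  set.seed(4)
  spikes <- cbind(n1 = rpois(m, 0.1), n2 = rep(0L, m))
  ex <- spikeExperiment(spikes, matrix(0, m, 1))
  d <- buildRegressors(ex)
  theta <- c(n2 = 0.5, bias = biasFor(0.1))
  J <- observedFisher(spikes[, 1], d, "n2", theta, 10)
  expect_true(all(J["n2", ] == 0) && all(J[, "n2"] == 0))
  expect_gt(J["bias", "bias"], 0)
})

test_that("Wald p-values match the chi-square(1) survival function", {
  # frozen chi-square(1) survival values: 3.8415 -> 0.05, 4.0 -> 0.0455
  wald <- SpikeNetGLM:::waldFromFisher
  p1 <- wald(c(x = sqrt(3.8415)), matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(unname(p1), 0.05, tolerance = 1e-3)
  p2 <- wald(c(x = 2), matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(unname(p2), 0.0455, tolerance = 1e-3)
  p0 <- wald(c(x = 0), matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(unname(p0), 1)
})

test_that("collinear regressors force p-values of one", {
  # two identical source neurons give identical design columns, so the
  # Fisher information is singular and the subset must be rejected
  set.seed(9)
  m <- 800L
  src <- rpois(m, 0.3)
  spikes <- cbind(n1 = rpois(m, 0.1), n2 = src, n3 = src)
  ex <- spikeExperiment(spikes, matrix(0, m, 1))
  d <- buildRegressors(ex)
  fit <- fitNeuronGLM(spikes[, 1], d, c("n2", "n3"))
  expect_true(all(waldPValues(fit, includeBias = FALSE) == 1))
})

test_that("BIC follows its defining formula", {
  expect_equal(bicScore(-50, 100, 3), 3 * log(100) + 100, tolerance = 1e-10)
  expect_equal(bicScore(-50, 100, 3), 113.8155, tolerance = 1e-4)
  expect_equal(bicScore(-7.5, 250, 0), 15)
  # a parent that leaves the likelihood unchanged costs exactly ln(m)
  expect_equal(bicScore(-50, 100, 4) - bicScore(-50, 100, 3), log(100))
})

test_that("log-likelihood is concave along random parameter segments", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 800, seed = 31)
  d <- buildRegressors(ex)
  y <- spikeCounts(ex)[, 1]
  pa <- c("n2", "s3")
  set.seed(77)
  for (r in 1:20) {
    th1 <- rnorm(3, 0, 0.5)
    th2 <- rnorm(3, 0, 0.5)
    a <- runif(1)
    f1 <- logLikelihood(y, d, pa, th1)
    f2 <- logLikelihood(y, d, pa, th2)
    fm <- logLikelihood(y, d, pa, a * th1 + (1 - a) * th2)
    expect_gte(fm, a * f1 + (1 - a) * f2 - 1e-8)
  }
})

test_that("Wald test is calibrated under the null", {
  # an independent noise regressor should be flagged at the 5% level
  # about 5% of the time
  nRep <- 1000L
  m <- 2000L
  hits <- logical(nRep)
  for (r in seq_len(nRep)) {
    set.seed(5000 + r)
    spikes <- cbind(n1 = rpois(m, 0.05), n2 = rpois(m, 0.05))
    ex <- spikeExperiment(spikes, matrix(0, m, 1))
    d <- buildRegressors(ex)
    fit <- SpikeNetGLM:::glmFitCore(spikes[, 1], d, "n2", 10)
    hits[r] <- fit$pValues[["n2"]] <= 0.05
  }
  expect_equal(mean(hits), 0.05, tolerance = 0.02 / 0.05)
})

test_that("approximate z-score prescreen behaves per its closed form", {
  # equal conditional rates: the log rate ratio vanishes
  y <- rep(c(1L, 0L, 1L, 0L), 50)
  reg <- rep(c(1, 1, 0, 0), 50)   # mean(y|on) == mean(y|off) == 0.5
  expect_equal(approxZscorePrescreen(y, reg, 10), 0)

  # Z^2 scales linearly with the number of active bins at fixed rates
  set.seed(12)
  y1 <- rpois(400, 0.2)
  r1 <- rep(c(1, 0), 200)
  z1 <- approxZscorePrescreen(y1, r1, 10)
  z2 <- approxZscorePrescreen(rep(y1, 2), rep(r1, 2), 10)
  expect_equal(z2^2 / z1^2, 2, tolerance = 1e-10)

  # uninformative cases return zero
  expect_equal(approxZscorePrescreen(c(0L, 0L, 1L), c(1, 1, 0), 10), 0)
  expect_error(approxZscorePrescreen(y1, rep(0, 400)), "active")
})

test_that("prescreen ranking tracks the full Wald ranking for strong edges", {
  truth <- twoParentNetwork()
  ex <- simulateUniform(truth, 4000, seed = 41)
  d <- buildRegressors(ex)
  y <- spikeCounts(ex)[, 1]
  valid <- seq.int(d@validFrom, nBins(ex))
  labs <- regressorLabels(d)
  z <- vapply(labs, function(j) {
    col <- d@matrix[valid, j]
    if (all(col == 0)) return(0)
    abs(approxZscorePrescreen(y[valid], col, 10))
  }, numeric(1))
  # the two true parents must rank inside the prescreen's retained set
  keep <- names(sort(z, decreasing = TRUE))[1:15]
  expect_true(all(c("n2", "s3") %in% keep))
})
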