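## Poisson GLM likelihood machinery: boxcar regressors, softplus-kappa
## nonlinearity, MLE, observed Fisher information, Wald tests, BIC, and the
## approximate z-score prescreen.

#' Softplus-kappa nonlinearity
#'
#' \code{lambda(eta) = log(1 + exp(kappa * eta)) / kappa}: approximately
#' exponential for low \code{eta}, asymptotically linear for large
#' \code{eta}, so inhibition saturates gracefully while excitation cannot
#' run away.  Computed overflow-safely.
#'
#' @param eta linear predictor (vectorized).
#' @param kappa positive calibration constant (default 10).
#' @return Positive rate(s), same shape as \code{eta}.
#' @examples
#' nonlinearity(0, 10)   # log(2)/10
#' @export
nonlinearity <- function(eta, kappa = 10) {
  stopifnot(kappa > 0)
  z <- kappa * eta
  out <- eta
  big <- z > 30
  out[big] <- eta[big] + log1p(exp(-z[big])) / kappa
  out[!big] <- log1p(exp(z[!big])) / kappa
  out
}

#' @rdname nonlinearity
#' @details \code{nonlinearityInverse} returns the \code{eta} whose rate is
#'   \code{lambda}: \code{log(expm1(kappa * lambda)) / kappa}.
#' @param lambda positive rate(s).
#' @export
nonlinearityInverse <- function(lambda, kappa = 10) {
  stopifnot(kappa > 0, all(lambda > 0))
  z <- kappa * lambda
  out <- lambda
  small <- z <= 30
  out[small] <- log(expm1(z[small])) / kappa
  out
}

## log(lambda(eta)), stable for very negative kappa*eta where
## lambda ~ exp(kappa*eta)/kappa.
logNonlinearity <- function(eta, kappa) {
  z <- kappa * eta
  out <- numeric(length(eta))
  lo <- z < -30
  out[lo] <- z[lo] - log(kappa)
  out[!lo] <- log(nonlinearity(eta[!lo], kappa))
  out
}

#' Build the boxcar regressor design
#'
#' Convolves each spike and stimulus column with its boxcar influence
#' window and appends an all-ones bias column.  The column for source j at
#' time t holds the sum of that source over bins \code{t - lower} through
#' \code{t - upper}.  Rows with incomplete history (the first
#' \code{max(lower)} bins) are flagged invalid and excluded from all
#' likelihood sums downstream.
#'
#' @param experiment a \linkS4class{SpikeExperiment}.
#' @param spikeWindow,stimWindow \linkS4class{BoxcarWindow}s for spike and
#'   stimulus history (defaults: bins t-5 ... t-2).
#' @return A \linkS4class{RegressorDesign}.
#' @export
buildRegressors <- function(experiment,
                            spikeWindow = boxcarWindow(5, 2),
                            stimWindow = boxcarWindow(5, 2)) {
  stopifnot(is(experiment, "SpikeExperiment"))
  m <- nBins(experiment)
  if (spikeWindow@lower >= m)
    stop("spike window (lower delay ", spikeWindow@lower,
         ") does not fit the series length ", m)
  if (stimWindow@lower >= m)
    stop("stimulus window (lower delay ", stimWindow@lower,
         ") does not fit the series length ", m)
  xh <- boxcarConvolve(spikeCounts(experiment), spikeWindow)
  ih <- boxcarConvolve(stimulusIndicators(experiment), stimWindow)
  mat <- cbind(xh, ih, bias = 1)
  labels <- c(colnames(spikeCounts(experiment)),
              colnames(stimulusIndicators(experiment)), "bias")
  colnames(mat) <- labels
  types <- c(rep("neuron", ncol(xh)), rep("stimulus", ncol(ih)), "bias")
  new("RegressorDesign", matrix = mat, labels = labels, types = types,
      validFrom = max(spikeWindow@lower, stimWindow@lower) + 1L,
      spikeWindow = spikeWindow, stimWindow = stimWindow)
}

## Column-wise boxcar sums via cumulative sums; rows without full history
## are zero-filled (they are excluded from fits via validFrom).
boxcarConvolve <- function(x, window) {
  x <- as.matrix(x)
  m <- nrow(x)
  cs <- apply(x, 2, cumsum)
  cs <- rbind(matrix(0, 1, ncol(x)), cs)  # cs[k + 1] = sum of rows 1..k
  t <- seq_len(m)
  hi <- pmax(t - window@upper, 0L)
  lo <- pmax(t - window@lower - 1L, 0L)
  out <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  out[t <= window@lower, ] <- 0
  dimnames(out) <- dimnames(x)
  out
}

#' Regressor labels of a design
#'
#' @param design a \linkS4class{RegressorDesign}.
#' @param types which column types to include.
#' @return Character vector of labels (bias excluded by default).
#' @export
regressorLabels <- function(design, types = c("neuron", "stimulus")) {
  design@labels[design@types %in% types]
}

#' Poisson GLM log-likelihood of one neuron
#'
#' Sum over valid bins of \code{X_c(t) log(lambda) - lambda}; the additive
#' constant \code{-log(X_c(t)!)} is dropped by convention, so absolute
#' values are comparable only within this package (differences and
#' deviances are unaffected).
#'
#' @param y spike-count series of the target neuron (full length).
#' @param design a \linkS4class{RegressorDesign}.
#' @param parentSet character labels of the regressors in the model.
#' @param theta parameter vector: weights for \code{parentSet}, bias last.
#' @param kappa nonlinearity constant.
#' @param rows optional row indices (subset of the valid rows) over which
#'   to evaluate; defaults to all valid rows.
#' @return Scalar log-likelihood.
#' @export
logLikelihood <- function(y, design, parentSet, theta, kappa = 10,
                          rows = NULL) {
  if (length(y) != nrow(design@matrix))
    stop("spike series length does not match the design (",
         length(y), " vs ", nrow(design@matrix), ")")
  rows <- designRows(design, rows)
  R <- design@matrix[rows, c(parentSet, "bias"), drop = FALSE]
  eta <- drop(R %*% theta)
  sum(y[rows] * logNonlinearity(eta, kappa) - nonlinearity(eta, kappa))
}

designRows <- function(design, rows) {
  valid <- seq.int(design@validFrom, nrow(design@matrix))
  if (is.null(rows)) return(valid)
  rows <- sort(as.integer(rows))
  if (any(rows < design@validFrom))
    stop("requested rows precede the first bin with full boxcar history")
  rows
}

designColumns <- function(design, parentSet) {
  if (anyDuplicated(parentSet))
    stop("duplicate regressor in subset: ",
         paste(unique(parentSet[duplicated(parentSet)]), collapse = ", "))
  missing <- setdiff(parentSet, design@labels)
  if (length(missing))
    stop("unknown regressor(s): ", paste(missing, collapse = ", "))
  if ("bias" %in% parentSet)
    stop("the bias is always included and cannot be named in the parent set")
  c(parentSet, "bias")
}

#' Maximum-likelihood fit of one neuron on a regressor subset
#'
#' Damped Newton ascent on the concave log-likelihood (gradient max-norm
#' below 1e-6 or relative log-likelihood change below 1e-9; at most 500
#' iterations).  The bias is always part of the model and is initialized
#' at the inverse nonlinearity of the empirical mean rate; a warm start
#' for the remaining weights can be supplied.
#'
#' @inheritParams logLikelihood
#' @param init optional named warm-start vector (weights and/or bias);
#'   unnamed entries are matched positionally to \code{c(parentSet, "bias")}.
#' @param maxit maximum Newton iterations.
#' @return A \linkS4class{NeuronFit} with the estimate, log-likelihood,
#'   observed Fisher information, Wald p-values and BIC.
#' @export
fitNeuronGLM <- function(y, design, parentSet = character(0), kappa = 10,
                         init = NULL, rows = NULL, maxit = 500L) {
  core <- glmFitCore(y, design, parentSet, kappa, init, rows, maxit)
  new("NeuronFit", theta = core$theta, parentSet = parentSet,
      logLik = core$logLik, fisher = core$fisher, pValues = core$pValues,
      bic = core$bic, mValid = core$mValid, converged = core$converged,
      iterations = core$iterations)
}

## Plain-list fit used by the selection/deviance hot loops (identical
## numbers to fitNeuronGLM without S4 construction overhead).
glmFitCore <- function(y, design, parentSet, kappa, init = NULL,
                       rows = NULL, maxit = 500L) {
  cols <- designColumns(design, parentSet)
  rows <- designRows(design, rows)
  R <- design@matrix[rows, cols, drop = FALSE]
  yv <- as.numeric(y[rows])
  p <- length(cols)
  theta0 <- numeric(p)
  mu <- max(mean(yv), 1e-4)
  theta0[p] <- nonlinearityInverse(mu, kappa)
  if (!is.null(init)) {
    if (is.null(names(init))) {
      stopifnot(length(init) == p)
      theta0 <- as.numeric(init)
    } else {
      hit <- intersect(names(init), cols)
      theta0[match(hit, cols)] <- init[hit]
    }
  }
  fit <- cpp_glm_newton(yv, R, kappa, theta0, maxit = maxit)
  theta <- setNames(drop(fit$theta), cols)
  J <- fit$fisher
  dimnames(J) <- list(cols, cols)
  J <- (J + t(J)) / 2
  pv <- waldFromFisher(theta, J)
  ll <- fit$loglik
  mValid <- length(rows)
  list(theta = theta, logLik = ll, fisher = J, pValues = pv,
       bic = bicScore(ll, mValid, length(parentSet)),
       mValid = as.integer(mValid), converged = isTRUE(fit$converged),
       iterations = as.integer(fit$iterations))
}

#' @rdname fitNeuronGLM
#' @param object a \code{NeuronFit}.
#' @param ... unused.
#' @export
setMethod("coef", "NeuronFit", function(object, ...) object@theta)

#' Observed Fisher information
#'
#' Closed-form observed Fisher information (the Hessian of the negative
#' log-likelihood) of the softplus-kappa Poisson GLM at a parameter value,
#' summed over valid rows.  The per-bin weight is
#' \code{y (lambda'/lambda)^2 + kappa (1 - y/lambda) s (1 - s)} with
#' \code{s = sigmoid(kappa eta)}.
#'
#' @inheritParams logLikelihood
#' @return Symmetric matrix with one row/column per parameter (bias last).
#' @export
observedFisher <- function(y, design, parentSet, theta, kappa = 10,
                           rows = NULL) {
  cols <- c(parentSet, "bias")
  rows <- designRows(design, rows)
  R <- design@matrix[rows, cols, drop = FALSE]
  eta <- drop(R %*% theta)
  s <- stats::plogis(kappa * eta)
  lam <- nonlinearity(eta, kappa)
  r <- ifelse(kappa * eta < -30, kappa, s / lam)
  yv <- as.numeric(y[rows])
  w <- yv * r^2 + kappa * (1 - yv / lam) * s * (1 - s)
  J <- crossprod(R, R * w)
  dimnames(J) <- list(cols, cols)
  (J + t(J)) / 2
}

## Wald p-values from an estimate and its observed Fisher information.
## A numerically singular Fisher matrix (reciprocal condition number below
## 1e-12) forces p = 1 for every parameter: near-singular information means
## at least one variance is arbitrarily large, so the subset is rejected
## under any p-value ceiling.
waldFromFisher <- function(theta, fisher, rcondTol = 1e-12) {
  p <- length(theta)
  ones <- setNames(rep(1, p), names(theta))
  if (p == 0L) return(numeric(0))
  rc <- tryCatch(rcond(fisher), error = function(e) 0)
  if (!is.finite(rc) || rc < rcondTol) return(ones)
  inv <- tryCatch(solve(fisher), error = function(e) NULL)
  if (is.null(inv)) return(ones)
  v <- diag(inv)
  bad <- !is.finite(v) | v <= 0
  stat <- rep(0, p)
  stat[!bad] <- theta[!bad]^2 / v[!bad]
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  pv[bad] <- 1
  setNames(pv, names(theta))
}

#' Wald p-values of a fit
#'
#' Per-parameter chi-square(1) Wald p-values
#' \code{P(chisq_1 >= theta_j^2 / [J^-1]_jj)}.  If the observed Fisher
#' information is numerically singular every p-value is 1 (guaranteed
#' rejection).
#'
#' @param fit a \linkS4class{NeuronFit}.
#' @param includeBias keep the bias entry (default TRUE).
#' @return Named p-value vector.
#' @export
waldPValues <- function(fit, includeBias = TRUE) {
  pv <- fit@pValues
  if (!includeBias) pv <- pv[names(pv) != "bias"]
  pv
}

#' Bayesian information criterion
#'
#' \code{log(mValid) * nParams - 2 * logLik}; \code{nParams} counts the
#' selected regressors only (the always-present bias is free), and
#' \code{mValid} is the number of likelihood-contributing bins.
#'
#' @param logLik maximized log-likelihood.
#' @param mValid number of contributing bins (>= 1).
#' @param nParams number of selected regressors.
#' @return Scalar BIC (smaller is better).
#' @export
bicScore <- function(logLik, mValid, nParams) {
  stopifnot(mValid >= 1)
  log(mValid) * nParams - 2 * logLik
}

#' Approximate z-score prescreen for a candidate regressor
#'
#' A closed-form approximation of the Wald z-score of a single regressor,
#' built from the target's conditional mean rates when the regressor is
#' active (\code{lambda_on}) versus inactive (\code{lambda_off}) and the
#' number of active bins M:
#' \deqn{Z^2 \approx (M / \kappa^2) \frac{(e^{\kappa \lambda_{on}} - 1)^2}
#'   {\lambda_{on} e^{2 \kappa \lambda_{on}}}
#'   \left[\log\frac{e^{\kappa \lambda_{on}} - 1}
#'   {e^{\kappa \lambda_{off}} - 1}\right]^2.}
#' Used only to rank and prune candidates before the forward search; never
#' to accept an edge.  Returns 0 (uninformative) when either conditional
#' rate is zero.
#'
#' @param y spike-count series of the target neuron.
#' @param regressor boxcar-summed candidate regressor column (same length).
#' @param kappa nonlinearity constant.
#' @return Signed approximate z-score (sign of the log rate ratio).
#' @export
approxZscorePrescreen <- function(y, regressor, kappa = 10) {
  on <- regressor != 0
  M <- sum(on)
  if (M == 0) stop("regressor is never active")
  lamOn <- mean(y[on])
  lamOff <- if (any(!on)) mean(y[!on]) else 0
  if (lamOn <= 0 || lamOff <= 0) return(0)
  num <- expm1(kappa * lamOn)
  den <- expm1(kappa * lamOff)
  lg <- log(num / den)
  z2 <- M / kappa^2 * num^2 / (lamOn * exp(2 * kappa * lamOn)) * lg^2
  sign(lg) * sqrt(z2)
}
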