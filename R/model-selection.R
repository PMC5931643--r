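## Elastic-forward BIC subset selection under a Wald p-value ceiling,
## with bootstrap subsample scoring, plus the oracle-lasso baseline.

#' Selection configuration
#'
#' Parameters of the elastic-forward regressor search.
#'
#' @param gamma Wald p-value ceiling for every selected regressor
#'   (0 < gamma < 1; default 0.01).
#' @param kMax maximum number of regressors proposed per step (default 5).
#' @param nu fraction of valid bins in each random subsample
#'   (0 < nu <= 1; default 0.7).
#' @param nSplits number of random subsamples per proposal step
#'   (default 10).
#' @param seed RNG seed controlling the subsamples; selection is
#'   deterministic given (data, seed).
#' @param prescreen if TRUE, keep only the top \code{3 * kMax} candidates
#'   by absolute approximate z-score before each proposal step (off by
#'   default).
#' @return A validated list of class \code{selectionConfig}.
#' @export
selectionConfig <- function(gamma = 0.01, kMax = 5L, nu = 0.7,
                            nSplits = 10L, seed = 1L, prescreen = FALSE) {
  stopifnot(gamma > 0, gamma < 1, kMax >= 1, nu > 0, nu <= 1, nSplits >= 1)
  structure(list(gamma = gamma, kMax = as.integer(kMax), nu = nu,
                 nSplits = as.integer(nSplits), seed = as.integer(seed),
                 prescreen = isTRUE(prescreen)),
            class = "selectionConfig")
}

#' Fit and score one regressor subset
#'
#' Bundled evaluation used by both the elastic-forward loop and the
#' proposal step: MLE, observed Fisher information, Wald p-values and BIC
#' for one neuron's regressor subset.
#'
#' @inheritParams fitNeuronGLM
#' @param subset regressor labels (no duplicates; bias implicit).
#' @return A \linkS4class{NeuronFit}.
#' @export
evaluateRegressors <- function(y, design, subset = character(0), kappa = 10,
                               init = NULL, rows = NULL) {
  fitNeuronGLM(y, design, parentSet = subset, kappa = kappa, init = init,
               rows = rows)
}

## p-value of the selected regressors only (bias unconstrained); empty
## set trivially satisfies any ceiling.
maxParentPValue <- function(fit) {
  pv <- waldPValues(fit, includeBias = FALSE)
  if (length(pv) == 0L) 0 else max(pv)
}

maxParentPValueCore <- function(fit) {
  pv <- fit$pValues[names(fit$pValues) != "bias"]
  if (length(pv) == 0L) 0 else max(pv)
}

## Draw the per-step random subsamples of valid rows (without
## replacement), seeded from (config seed, step index).
drawSplits <- function(design, config, step) {
  valid <- seq.int(design@validFrom, nrow(design@matrix))
  nTake <- max(1L, floor(config$nu * length(valid)))
  if (config$nu == 1 && config$nSplits == 1L) return(list(valid))
  withSeed(subSeed(config$seed, 131L, step), {
    lapply(seq_len(config$nSplits), function(i)
      sort(sample(valid, nTake, replace = FALSE)))
  })
}

#' Propose candidate regressors for one forward step
#'
#' Every regressor outside the current set is fitted jointly with the
#' current set on each random subsample and on the full data.  A
#' candidate's p-value score is \code{max(median over subsamples,
#' full-data value)} of its own Wald p-value, and its BIC score is the
#' same aggregation of the subset BICs; the max acts as a safeguard
#' against regressors that only look good on some subsamples.  Candidates
#' with BIC score below the current BIC and p-value score below gamma are
#' returned, at most \code{kMax}, sorted by ascending BIC score with ties
#' broken by regressor index.
#'
#' @inheritParams fitNeuronGLM
#' @param current currently selected regressor labels.
#' @param config a \code{\link{selectionConfig}}.
#' @param baseBIC full-data BIC of the current set.
#' @param step proposal step index (folds into the subsample seed).
#' @param warmTheta optional warm-start coefficients of the current fit.
#' @return data.frame with columns candidate, bicScore, pvalScore
#'   (possibly zero rows).
#' @export
forwardModelProposal <- function(y, design, current, config, baseBIC,
                                 kappa = 10, step = 1L, warmTheta = NULL) {
  candidates <- setdiff(regressorLabels(design), current)
  if (length(candidates) == 0L)
    return(data.frame(candidate = character(0), bicScore = numeric(0),
                      pvalScore = numeric(0)))
  if (isTRUE(config$prescreen) && length(candidates) > 3L * config$kMax) {
    valid <- seq.int(design@validFrom, nrow(design@matrix))
    zs <- vapply(candidates, function(j) {
      col <- design@matrix[valid, j]
      if (all(col == 0)) return(0)
      abs(approxZscorePrescreen(y[valid], col, kappa))
    }, numeric(1))
    keep <- order(-zs, match(candidates, design@labels))[seq_len(3L * config$kMax)]
    candidates <- candidates[sort(keep)]
  }
  splits <- drawSplits(design, config, step)
  bicScoreV <- pvalScoreV <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    j <- candidates[i]
    subset <- c(current, j)
    full <- glmFitCore(y, design, subset, kappa, init = warmTheta)
    pj <- unname(full$pValues[j])
    bj <- full$bic
    if (config$nu == 1 && config$nSplits == 1L) {
      pvalScoreV[i] <- pj
      bicScoreV[i] <- bj
    } else {
      ps <- bs <- numeric(length(splits))
      for (k in seq_along(splits)) {
        fs <- glmFitCore(y, design, subset, kappa,
                         init = full$theta, rows = splits[[k]])
        ps[k] <- unname(fs$pValues[j])
        bs[k] <- fs$bic
      }
      pvalScoreV[i] <- max(median(ps), pj)
      bicScoreV[i] <- max(median(bs), bj)
    }
  }
  ok <- bicScoreV < baseBIC & pvalScoreV < config$gamma
  out <- data.frame(candidate = candidates[ok], bicScore = bicScoreV[ok],
                    pvalScore = pvalScoreV[ok], stringsAsFactors = FALSE)
  out <- out[order(out$bicScore, match(out$candidate, design@labels)), ,
             drop = FALSE]
  utils::head(out, config$kMax)
}

#' Elastic-forward regressor selection for one neuron
#'
#' Starting from the empty parent set, alternates a proposal step with an
#' elastic shrink loop: the top-n proposed candidates are added jointly
#' and n shrinks by one until the joint model both satisfies the p-value
#' ceiling and improves the best BIC found; the search stops when no
#' candidate qualifies.  Rerunning from scratch on grown data can drop
#' previously accepted edges, which is how edge removal between
#' acquisitions is realized.
#'
#' @inheritParams fitNeuronGLM
#' @param config a \code{\link{selectionConfig}}.
#' @return A \linkS4class{SelectionResult}; its fit satisfies
#'   \code{max(waldPValues) <= gamma} over the parent set and its BIC
#'   never exceeds the bias-only BIC.
#' @export
elasticForwardSelect <- function(y, design, config = selectionConfig(),
                                 kappa = 10) {
  current <- character(0)
  history <- list()
  step <- 0L
  fitCur <- glmFitCore(y, design, current, kappa)
  nr <- length(regressorLabels(design))
  repeat {
    step <- step + 1L
    if (step > nr + 1L) break  # defensive; each step adds >= 1 regressor
    prop <- tryCatch(
      forwardModelProposal(y, design, current, config, fitCur$bic, kappa,
                           step = step, warmTheta = fitCur$theta),
      error = function(e) {
        warning("proposal step failed: ", conditionMessage(e))
        data.frame(candidate = character(0))
      })
    if (nrow(prop) == 0L) break
    n <- nrow(prop)
    rBest <- current
    fitBest <- fitCur
    success <- FALSE
    while (n >= 0L) {
      if (n == 0L) {
        fitTry <- fitCur
      } else {
        rTry <- c(current, prop$candidate[seq_len(n)])
        fitTry <- tryCatch(
          glmFitCore(y, design, rTry, kappa, init = fitCur$theta),
          error = function(e) NULL)
        if (is.null(fitTry) || !fitTry$converged) { n <- n - 1L; next }
      }
      if (n > 0L && maxParentPValueCore(fitTry) <= config$gamma &&
          fitTry$bic <= fitBest$bic) {
        rBest <- c(current, prop$candidate[seq_len(n)])
        fitBest <- fitTry
      }
      if (fitTry$bic >= fitBest$bic && !identical(rBest, current)) {
        success <- TRUE
        history[[length(history) + 1L]] <- data.frame(
          step = step, added = paste(setdiff(rBest, current), collapse = ","),
          bic = fitBest$bic, stringsAsFactors = FALSE)
        current <- rBest
        fitCur <- fitBest
        break
      }
      n <- n - 1L
    }
    if (!success) break
  }
  hist <- if (length(history)) do.call(rbind, history) else
    data.frame(step = integer(0), added = character(0), bic = numeric(0))
  fitS4 <- new("NeuronFit", theta = fitCur$theta, parentSet = current,
               logLik = fitCur$logLik, fisher = fitCur$fisher,
               pValues = fitCur$pValues, bic = fitCur$bic,
               mValid = fitCur$mValid, converged = fitCur$converged,
               iterations = fitCur$iterations)
  new("SelectionResult", parentSet = current, fit = fitS4,
      history = hist, config = unclass(config))
}

#' Select parents for every neuron and assemble the network
#'
#' Runs \code{\link{elasticForwardSelect}} per neuron (each with a
#' neuron-specific sub-seed) and assembles the fitted weights into a
#' \linkS4class{NetworkModel}.
#'
#' @param experiment a \linkS4class{SpikeExperiment}.
#' @param config a \code{\link{selectionConfig}}.
#' @param kappa nonlinearity constant.
#' @param spikeWindow,stimWindow boxcar windows.
#' @param design optional prebuilt \linkS4class{RegressorDesign}.
#' @return list with elements \code{selections} (per-neuron
#'   \linkS4class{SelectionResult}) and \code{model}
#'   (\linkS4class{NetworkModel}).
#' @export
fitNetwork <- function(experiment, config = selectionConfig(), kappa = 10,
                       spikeWindow = boxcarWindow(5, 2),
                       stimWindow = boxcarWindow(5, 2), design = NULL) {
  if (is.null(design))
    design <- buildRegressors(experiment, spikeWindow, stimWindow)
  counts <- spikeCounts(experiment)
  sel <- vector("list", ncol(counts))
  names(sel) <- colnames(counts)
  for (c in seq_len(ncol(counts))) {
    cfg <- config
    cfg$seed <- subSeed(config$seed, c)
    sel[[c]] <- elasticForwardSelect(counts[, c], design, cfg, kappa)
  }
  list(selections = sel,
       model = networkFromSelections(sel, design, kappa))
}

#' Assemble a NetworkModel from per-neuron selections
#'
#' @param selections named list of \linkS4class{SelectionResult}, one per
#'   neuron, in neuron order.
#' @param design the \linkS4class{RegressorDesign} they were fitted on.
#' @param kappa nonlinearity constant.
#' @return A \linkS4class{NetworkModel}.
#' @export
networkFromSelections <- function(selections, design, kappa = 10) {
  neurons <- design@labels[design@types == "neuron"]
  stims <- design@labels[design@types == "stimulus"]
  nc <- length(neurons); ns <- length(stims)
  W <- matrix(0, nc, nc, dimnames = list(neurons, neurons))
  H <- matrix(0, ns, nc, dimnames = list(stims, neurons))
  b <- numeric(nc)
  for (c in seq_len(nc)) {
    th <- selections[[c]]@fit@theta
    b[c] <- th[["bias"]]
    for (lab in selections[[c]]@parentSet) {
      if (lab %in% neurons) W[lab, c] <- th[[lab]]
      else H[lab, c] <- th[[lab]]
    }
  }
  networkModel(W, H, b, kappa, design@spikeWindow, design@stimWindow)
}

#' L1-penalized (lasso) baseline
#'
#' Maximizes the penalized likelihood \code{logLik - l1 (|W_c|_1 + |H_c|_1)}
#' (bias unpenalized) by proximal-gradient ascent with backtracking,
#' warm-started along a descending penalty grid.  Returns the nonzero
#' support per penalty; used as the comparison baseline for the
#' elastic-forward search.
#'
#' @inheritParams fitNeuronGLM
#' @param l1Grid positive penalties, descending.
#' @param tol support threshold: entries with |w| below it count as zero.
#' @param maxit proximal-gradient iterations per grid point.
#' @return list with \code{supports} (list of label vectors per penalty),
#'   \code{coefs} (matrix of coefficients, one column per penalty) and
#'   \code{l1Grid}.
#' @export
lassoBaseline <- function(y, design, l1Grid, kappa = 10, tol = 1e-6,
                          maxit = 400L) {
  stopifnot(all(l1Grid >= 0), !is.unsorted(rev(l1Grid)))
  rows <- designRows(design, NULL)
  labs <- regressorLabels(design)
  cols <- c(labs, "bias")
  R <- design@matrix[rows, cols, drop = FALSE]
  yv <- as.numeric(y[rows])
  p <- ncol(R)
  theta <- numeric(p)
  theta[p] <- nonlinearityInverse(max(mean(yv), 1e-4), kappa)
  coefs <- cpp_lasso_path(yv, R, kappa, as.numeric(l1Grid), theta,
                          maxit = maxit)
  dimnames(coefs) <- list(cols, NULL)
  supports <- lapply(seq_along(l1Grid), function(gi)
    labs[abs(coefs[labs, gi]) > tol])
  list(supports = supports, coefs = coefs, l1Grid = l1Grid)
}

#' Oracle-lasso network recovery
#'
#' Fits the lasso baseline for every neuron over a shared penalty grid and
#' picks the grid point whose network-level support maximizes F1 against a
#' supplied ground truth (the "oracle" choice of the l1 penalty).
#'
#' @param experiment a \linkS4class{SpikeExperiment}.
#' @param truth a \linkS4class{GroundTruthNetwork} (or NetworkModel).
#' @param l1Grid positive penalties, descending; a default geometric grid
#'   is used when NULL.
#' @param kappa nonlinearity constant.
#' @param design optional prebuilt design.
#' @return list with \code{f1} (best F1), \code{l1} (the oracle penalty),
#'   \code{metrics} (the \code{\link{edgeRecoveryMetrics}} at the oracle
#'   point) and \code{supports} (per-neuron parent labels at that point).
#' @export
oracleLasso <- function(experiment, truth, l1Grid = NULL, kappa = 10,
                        design = NULL) {
  if (is.null(design)) design <- buildRegressors(experiment,
                                                 truth@spikeWindow,
                                                 truth@stimWindow)
  counts <- spikeCounts(experiment)
  if (is.null(l1Grid)) {
    # data-adaptive grid: the largest penalty is the one that zeroes every
    # regressor (max absolute null-model score over neurons), descending
    # geometrically over two and a half decades
    l1Max <- max(vapply(seq_len(ncol(counts)), function(c)
      lassoNullScore(counts[, c], design, kappa), numeric(1)))
    l1Grid <- l1Max * 1.02 * 10^seq(0, -2.5, length.out = 9)
  }
  perNeuron <- lapply(seq_len(ncol(counts)), function(c)
    lassoBaseline(counts[, c], design, l1Grid, kappa))
  best <- list(f1 = -1, gi = 1L)
  for (gi in seq_along(l1Grid)) {
    supports <- lapply(perNeuron, function(x) x$supports[[gi]])
    met <- edgeRecoveryMetrics(supportsToModel(supports, design, kappa), truth)
    if (met$combined["f1"] > best$f1) best <- list(f1 = met$combined[["f1"]],
                                                   gi = gi, metrics = met)
  }
  supports <- lapply(perNeuron, function(x) x$supports[[best$gi]])
  list(f1 = best$f1, l1 = l1Grid[best$gi], metrics = best$metrics,
       supports = supports)
}

## Max absolute likelihood score of the regressors at the bias-only MLE;
## any penalty above it leaves the lasso support empty.
lassoNullScore <- function(y, design, kappa = 10) {
  rows <- designRows(design, NULL)
  labs <- regressorLabels(design)
  R <- design@matrix[rows, c(labs, "bias"), drop = FALSE]
  yv <- as.numeric(y[rows])
  b0 <- nonlinearityInverse(max(mean(yv), 1e-4), kappa)
  eta <- rep(b0, length(yv))
  s <- stats::plogis(kappa * eta)
  lam <- nonlinearity(eta, kappa)
  g <- drop(crossprod(R[, labs, drop = FALSE], yv * (s / lam)[1] - s[1]))
  max(abs(g))
}

## Presence-only model from per-neuron support sets (weights set to 1).
supportsToModel <- function(supports, design, kappa = 10) {
  neurons <- design@labels[design@types == "neuron"]
  stims <- design@labels[design@types == "stimulus"]
  nc <- length(neurons); ns <- length(stims)
  W <- matrix(0, nc, nc, dimnames = list(neurons, neurons))
  H <- matrix(0, ns, nc, dimnames = list(stims, neurons))
  for (c in seq_len(nc)) {
    for (lab in supports[[c]]) {
      if (lab %in% neurons) W[lab, c] <- 1 else H[lab, c] <- 1
    }
  }
  networkModel(W, H, numeric(nc), kappa, design@spikeWindow, design@stimWindow)
}
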