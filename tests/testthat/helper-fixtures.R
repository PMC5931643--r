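# Shared fixtures and independent oracles, all built in code at test time.

# evaluation-speed selection configuration used across simulation tests
fastCfg <- function(seed, ...) {
  selectionConfig(nSplits = 5L, prescreen = TRUE, seed = seed, ...)
}

biasFor <- function(rate, kappa = 10) nonlinearityInverse(rate, kappa)

# zero-edge network: every neuron independent of every regressor
nullNetwork <- function(nNeurons = 18L, nStimuli = 30L, rate = 0.05) {
  networkModel(matrix(0, nNeurons, nNeurons),
               matrix(0, nStimuli, nNeurons),
               rep(biasFor(rate), nNeurons))
}

# one target neuron driven by one neuron parent and one stimulus parent
twoParentNetwork <- function(rate = 0.05) {
  W <- matrix(0, 18, 18)
  H <- matrix(0, 30, 18)
  W[2, 1] <- rateIncrementToWeight(0.05, rate)
  H[3, 1] <- rateIncrementToWeight(0.10, rate)
  networkModel(W, H, rep(biasFor(rate), 18))
}

simulateUniform <- function(truth, m, seed) {
  stim <- generateStimulusSequence(nStimuli(truth), m, seed = seed)
  simulatePoissonNetwork(truth, stim, seed = seed + 1L)
}

# central-difference Hessian of the negative log-likelihood; the
# independent oracle for the closed-form observed Fisher information
finiteDiffFisher <- function(y, design, parentSet, theta, kappa, h = 1e-4) {
  f <- function(th) -logLikelihood(y, design, parentSet, th, kappa)
  p <- length(theta)
  Hm <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(a)) {
      ea <- eb <- numeric(p)
      ea[a] <- h; eb[b] <- h
      v <- (f(theta + ea + eb) - f(theta + ea - eb) -
              f(theta - ea + eb) + f(theta - ea - eb)) / (4 * h^2)
      Hm[a, b] <- Hm[b, a] <- v
    }
  }
  Hm
}

# independent brute-force motif classifier: tests a triad's directed
# adjacency against explicit canonical motif matrices under all vertex
# permutations, with reciprocal-pair fallbacks spelled out separately
# from the package's vectorized rules
bruteClassifyTriad <- function(A) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  U <- (A | t(A)); diag(U) <- FALSE
  if (sum(U) / 2 < 2 || any(rowSums(U) == 0)) return(NA_character_)
  mat <- function(edges) {
    M <- matrix(FALSE, 3, 3)
    for (e in edges) M[e[1], e[2]] <- TRUE
    M
  }
  iso <- function(target) {
    for (p in perms) if (identical(unname(A[p, p]), target)) return(TRUE)
    FALSE
  }
  if (sum(U) / 2 == 2) {
    if (iso(mat(list(c(1, 2), c(1, 3))))) return("divergent")
    if (iso(mat(list(c(2, 1), c(3, 1))))) return("convergent")
    return("chain")
  }
  hasCycle <- FALSE
  for (p in perms)
    if (A[p[1], p[2]] && A[p[2], p[3]] && A[p[3], p[1]]) hasCycle <- TRUE
  if (hasCycle) "cycle" else "triangle"
}

bruteMotifCensus <- function(W) {
  A <- (as.matrix(W) != 0)
  diag(A) <- FALSE
  counts <- setNames(numeric(5),
                     c("divergent", "convergent", "chain", "triangle", "cycle"))
  n <- nrow(A)
  if (n >= 3) {
    for (tr in asplit(combn(n, 3), 2)) {
      cl <- bruteClassifyTriad(A[tr, tr])
      if (!is.na(cl)) counts[cl] <- counts[cl] + 1
    }
  }
  counts
}

# brute-force maximal cliques by subset enumeration (feasible to ~12 nodes)
bruteMaxCliques <- function(U, minSize = 2L) {
  n <- nrow(U)
  cliques <- list()
  isClique <- function(nodes) {
    if (length(nodes) < 2) return(TRUE)
    all(U[t(combn(nodes, 2))])
  }
  for (size in n:minSize) {
    if (size > n) next
    for (nodes in asplit(combn(n, size), 2)) {
      nodes <- as.integer(nodes)
      if (!isClique(nodes)) next
      contained <- any(vapply(cliques, function(cl)
        all(nodes %in% cl), logical(1)))
      if (!contained) cliques[[length(cliques) + 1L]] <- nodes
    }
  }
  cliques
}
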