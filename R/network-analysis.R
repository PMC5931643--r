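## Motif triplet census, degree distributions, clique membership, and the
## small-world null-ensemble comparison.

## The five motif triplet classes.  Edge weight and sign are ignored; a
## triplet is examined only if its undirected skeleton is connected.
## Classification is direction-aware on the skeleton:
##
##   divergent    a -> b, a -> c         (one source feeds both others)
##   convergent   a -> c, b -> c         (both feed one sink)
##   chain        a -> b -> c            (two skeleton edges, mixed
##                                        directions or any reciprocal pair)
##   triangle     three skeleton edges, no directed 3-cycle
##   cycle        three skeleton edges containing a directed 3-cycle
##
## Reciprocal pairs are folded into the chain/triangle/cycle classes by
## these rules, so every connected triplet maps to exactly one class.
motifClassNames <- c("divergent", "convergent", "chain", "triangle", "cycle")

## Classify one triplet given the 3x3 directed presence matrix.
classifyTriad <- function(A) {
  U <- (A | t(A)); diag(U) <- FALSE
  nSkel <- sum(U) / 2
  deg <- rowSums(U)
  if (nSkel < 2 || any(deg == 0)) return(NA_character_)
  if (nSkel == 2) {
    center <- which(deg == 2)
    others <- which(deg == 1)
    outOnly <- all(A[center, others]) && !any(A[others, center])
    inOnly <- all(A[others, center]) && !any(A[center, others])
    if (outOnly) return("divergent")
    if (inOnly) return("convergent")
    return("chain")
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms)
    if (A[p[1], p[2]] && A[p[2], p[3]] && A[p[3], p[1]]) return("cycle")
  "triangle"
}

#' Motif triplet census
#'
#' Enumerates every 3-node combination of the network, keeps those whose
#' undirected skeleton is connected, and classifies each into one of five
#' motif classes (divergent, convergent, chain, acyclic triangle, cyclic
#' triangle); edge weights and signs are ignored.  Exhaustive; the census
#' total never exceeds choose(n, 3).
#'
#' @param W square adjacency (weight) matrix; nonzero = edge.  The
#'   diagonal is ignored.
#' @return list with \code{counts} (named vector over the five classes)
#'   and \code{nTriples} (connected triplets examined).
#' @export
motifCensus <- function(W) {
  A <- (as.matrix(W) != 0)
  diag(A) <- FALSE
  n <- nrow(A)
  counts <- setNames(numeric(5), motifClassNames)
  if (n < 3) return(list(counts = counts, nTriples = 0L))
  trip <- combn(n, 3)
  i <- trip[1, ]; j <- trip[2, ]; k <- trip[3, ]
  # directed presence bits of the three ordered pairs, fully vectorized
  aij <- A[cbind(i, j)]; aji <- A[cbind(j, i)]
  aik <- A[cbind(i, k)]; aki <- A[cbind(k, i)]
  ajk <- A[cbind(j, k)]; akj <- A[cbind(k, j)]
  uij <- aij | aji; uik <- aik | aki; ujk <- ajk | akj
  nSkel <- uij + uik + ujk
  # two skeleton edges: the node on both of them is the center
  centerI <- nSkel == 2 & !ujk   # edges i-j and i-k
  centerJ <- nSkel == 2 & !uik
  centerK <- nSkel == 2 & !uij
  divergent <-
    (centerI & aij & aik & !aji & !aki) |
    (centerJ & aji & ajk & !aij & !akj) |
    (centerK & aki & akj & !aik & !ajk)
  convergent <-
    (centerI & aji & aki & !aij & !aik) |
    (centerJ & aij & akj & !aji & !ajk) |
    (centerK & aik & ajk & !aki & !akj)
  chain <- nSkel == 2 & !divergent & !convergent
  # three skeleton edges: a directed 3-cycle exists in one of the two
  # rotation directions
  cyc <- nSkel == 3 & ((aij & ajk & aki) | (aik & akj & aji))
  triangle <- nSkel == 3 & !cyc
  counts["divergent"] <- sum(divergent)
  counts["convergent"] <- sum(convergent)
  counts["chain"] <- sum(chain)
  counts["triangle"] <- sum(triangle)
  counts["cycle"] <- sum(cyc)
  list(counts = counts, nTriples = as.integer(sum(counts)))
}

#' Degree distributions
#'
#' Per-node degree counts of the presence graph: all edges (distinct
#' neighbours in either direction), outbound edges (children) and inbound
#' edges (parents).
#'
#' @param W square adjacency matrix; nonzero = edge, diagonal ignored.
#' @return data.frame with columns node, all, out, in_.
#' @export
degreeDistributions <- function(W) {
  A <- (as.matrix(W) != 0)
  diag(A) <- FALSE
  U <- A | t(A)
  data.frame(node = seq_len(nrow(A)), all = rowSums(U),
             out = rowSums(A), in_ = colSums(A))
}

#' Maximal-clique membership per node
#'
#' Enumerates maximal cliques (size >= 2) of the symmetrized presence
#' graph and counts, per node, how many maximal cliques it belongs to,
#' overall and broken down by clique size; also the fraction of nodes
#' participating in two or more cliques.
#'
#' @param W square adjacency matrix; nonzero = edge, diagonal ignored.
#' @param minSize smallest clique size counted (default 2).
#' @return list with \code{perNode} (count vector), \code{bySize}
#'   (nodes x clique-size matrix), \code{cliques} (list of node sets) and
#'   \code{fractionMultiple}.
#' @export
cliqueMembership <- function(W, minSize = 2L) {
  A <- (as.matrix(W) != 0)
  diag(A) <- FALSE
  U <- A | t(A)
  g <- igraph::graph_from_adjacency_matrix(U, mode = "undirected")
  cl <- igraph::max_cliques(g, min = minSize)
  n <- nrow(A)
  perNode <- numeric(n)
  sizes <- vapply(cl, length, integer(1))
  maxSize <- if (length(sizes)) max(sizes) else minSize
  bySize <- matrix(0, n, maxSize,
                   dimnames = list(NULL, paste0("size", seq_len(maxSize))))
  for (i in seq_along(cl)) {
    nodes <- as.integer(cl[[i]])
    perNode[nodes] <- perNode[nodes] + 1
    bySize[nodes, sizes[i]] <- bySize[nodes, sizes[i]] + 1
  }
  list(perNode = perNode, bySize = bySize,
       cliques = lapply(cl, as.integer),
       fractionMultiple = mean(perNode >= 2))
}

#' Small-world null-ensemble test
#'
#' Simulates an ensemble of small-world networks matched in node count
#' and directed edge density, computes a statistic vector on each (by
#' default the motif census), and returns the Gaussian-approximation
#' z-score and two-sided p-value of each observed statistic against the
#' ensemble mean and standard deviation.  Degenerate statistics (zero
#' ensemble spread) report NA.
#'
#' @param observedStats named numeric vector of observed statistics.
#' @param nNodes,density matched network size and directed edge density.
#' @param nSims ensemble size (>= 100).
#' @param seed RNG seed; deterministic per seed.
#' @param statFun function(W) returning a numeric vector conformable
#'   with \code{observedStats}; default is the motif census counts.
#' @param rewireProb rewiring probability of the null generator.
#' @return data.frame with statistic, observed, mean, sd, z, p.
#' @export
smallWorldNullTest <- function(observedStats, nNodes, density, nSims = 200L,
                               seed = 1L, statFun = NULL, rewireProb = 0.1) {
  stopifnot(nSims >= 100)
  if (is.null(statFun)) statFun <- function(W) motifCensus(W)$counts
  sims <- withSeed(seed, {
    vapply(seq_len(nSims), function(i) {
      e <- ringLatticeEdges(nNodes, density, rewireProb)
      W <- matrix(0, nNodes, nNodes)
      if (nrow(e)) W[e] <- 1
      as.numeric(statFun(W))
    }, numeric(length(observedStats)))
  })
  mu <- rowMeans(sims)
  sdv <- apply(sims, 1, sd)
  z <- ifelse(sdv > 0, (as.numeric(observedStats) - mu) / sdv, NA_real_)
  p <- ifelse(is.na(z), NA_real_, 2 * pnorm(-abs(z)))
  data.frame(statistic = names(observedStats), observed = as.numeric(observedStats),
             mean = mu, sd = sdv, z = z, p = p, row.names = NULL)
}
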