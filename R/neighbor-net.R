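#' @include AllClasses.R utils.R marker-selection.R
NULL

#' Uncorrected p-distance matrix from an alignment
#'
#' @param aln a [DNAAlignment-class] or coercible.
#' @param deletion `"pairwise"` (default) or `"complete"` site deletion.
#' @return symmetric numeric distance matrix with taxon dimnames. A pair
#'   with no comparable sites raises an error naming the pair.
#' @export
pDistanceMatrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- alignmentMatrix(aln)
  pairwisePDistances(m, deletion)
}

validateDistanceMatrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  d
}

#' Neighbour-Net circular split system
#'
#' Agglomerative Neighbour-Net: taxa are clustered with a neighbour-joining
#' style selection criterion applied first between cluster chains, then
#' between their endpoint nodes; interior nodes of growing chains are
#' eliminated by the 3-point reduction (`u = 2/3 x + 1/3 y`,
#' `v = 2/3 z + 1/3 y`), and the expansion of the final chain yields a
#' circular ordering of the taxa. All `n(n-1)/2` interval splits of that
#' ordering are candidates; their weights are estimated by nonnegative
#' least squares (Lawson-Hanson active set) against the observed
#' distances. Splits with weight at most `eps` times the mean candidate
#' weight are dropped, and an optional dimension filter greedily removes
#' the lowest-weight splits until no `maxDim + 1` splits are mutually
#' incompatible.
#'
#' On a tree metric the result is exactly the tree's splits with weights
#' equal to the branch lengths.
#'
#' @param d symmetric distance matrix (e.g. from [pDistanceMatrix()]),
#'   at least 4 taxa.
#' @param maxDim dimension filter (default 4); `Inf` disables it.
#' @param eps relative weight threshold for dropping splits, default 1e-6.
#' @return a [SplitSystem-class] with `circularOrder` set.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
#' d <- ape::cophenetic.phylo(tr)
#' nn <- neighborNet(d)
#' nSplits(nn)   # 5: four trivial + AB|CD
#' @export
neighborNet <- function(d, maxDim = 4, eps = 1e-6) {
  d <- validateDistanceMatrix(d)
  n <- nrow(d)
  if (n < 4L) stop("Neighbour-Net needs at least 4 taxa")
  ord <- nnOrdering(unname(d))
  # rotate so that taxon 1 leads (cosmetic; the cycle is unchanged)
  i1 <- match(1L, ord)
  ord <- c(ord[i1:n], ord[seq_len(i1 - 1L)])
  cand <- nnCandidateSplits(ord)
  w <- nnlsSplitWeights(cand, d)
  keep <- w > eps * mean(w)
  sides <- lapply(cand[keep], canonicalSide, n = n)
  ss <- splitSystem(rownames(d), sides, w[keep], circularOrder = ord)
  if (is.finite(maxDim)) ss <- dimensionFilter(ss, maxDim)
  ss
}

# the agglomerative ordering phase of Neighbour-Net.
# Node ids are reused in place when the 3-point reduction eliminates a
# chain-interior node, so D stays n x n throughout. Each cluster keeps its
# ordered chain of original taxa and its one or two active endpoint nodes
# (active[1] = chain start, active[2] = chain end).
nnOrdering <- function(d) {
  n <- nrow(d)
  if (n <= 3L) return(seq_len(n))
  D <- unname(d)
  cl <- lapply(seq_len(n), function(i) list(active = i, chain = i))
  reduce3 <- function(x, y, z) {   # eliminate interior node y
    u <- 2 / 3 * D[x, ] + 1 / 3 * D[y, ]
    v <- 2 / 3 * D[z, ] + 1 / 3 * D[y, ]
    uv <- (D[x, y] + D[x, z] + D[y, z]) / 3
    D[x, ] <<- u; D[, x] <<- u
    D[z, ] <<- v; D[, z] <<- v
    D[x, z] <<- uv; D[z, x] <<- uv
    D[x, x] <<- 0; D[z, z] <<- 0
    D[y, ] <<- 0; D[, y] <<- 0
  }
  while (length(cl) > 1L) {
    m <- length(cl)
    if (m == 2L) {
      sel <- c(1L, 2L)
    } else {
      CD <- matrix(0, m, m)
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
        CD[i, j] <- CD[j, i] <- mean(D[cl[[i]]$active, cl[[j]]$active])
      r <- rowSums(CD) / (m - 2L)
      Q <- CD - outer(r, r, `+`)
      diag(Q) <- Inf
      sel <- sort(arrayInd(which.min(Q), dim(Q))[1L, ])
    }
    A <- cl[[sel[1L]]]; B <- cl[[sel[2L]]]
    others <- cl[-sel]
    n1 <- length(A$active); n2 <- length(B$active)
    if (n1 == 1L && n2 == 1L) {
      newcl <- list(active = c(A$active, B$active),
                    chain = c(A$chain, B$chain))
    } else {
      nodes <- c(A$active, B$active)
      ltmp <- n1 + n2 + length(others)
      R <- vapply(seq_along(nodes), function(i) {
        x <- nodes[i]
        sum(D[x, nodes[-i]]) +
          sum(vapply(others, function(C) mean(D[x, C$active]), 0))
      }, 0)
      if (ltmp > 2L) R <- R / (ltmp - 2L)
      bestQ <- Inf; xi <- yi <- 1L
      for (i in seq_len(n1)) for (j in seq_len(n2)) {
        q <- D[nodes[i], nodes[n1 + j]] - R[i] - R[n1 + j]
        if (q < bestQ - 1e-12) { bestQ <- q; xi <- i; yi <- j }
      }
      x <- A$active[xi]; y <- B$active[yi]
      # orient chains so that x is A's right end and y is B's left end
      chainA <- A$chain; aFar <- if (n1 == 2L) A$active[3L - xi] else x
      if (n1 == 2L && xi == 1L) chainA <- rev(chainA)
      chainB <- B$chain; bFar <- if (n2 == 2L) B$active[3L - yi] else y
      if (n2 == 2L && yi == 2L) chainB <- rev(chainB)
      if (n1 == 2L && n2 == 2L) {
        reduce3(aFar, x, y)
        reduce3(aFar, y, bFar)
        act <- c(aFar, bFar)
      } else if (n1 == 2L) {       # path aFar - x - y
        reduce3(aFar, x, y)
        act <- c(aFar, y)
      } else {                     # path x - y - bFar
        reduce3(x, y, bFar)
        act <- c(x, bFar)
      }
      newcl <- list(active = act, chain = c(chainA, chainB))
    }
    cl[[sel[1L]]] <- newcl
    cl <- cl[-sel[2L]]
  }
  cl[[1L]]$chain
}

# all interval splits of a circular ordering, as sides excluding ord[1]
nnCandidateSplits <- function(ord) {
  n <- length(ord)
  out <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in 2:n) for (j in i:n) {
    k <- k + 1L
    out[[k]] <- sort(ord[i:j])
  }
  out
}

# nonnegative least-squares weights for candidate sides against observed d
nnlsSplitWeights <- function(sides, d) {
  n <- nrow(d)
  pr <- which(upper.tri(d), arr.ind = TRUE)
  A <- matrix(0, nrow(pr), length(sides))
  for (s in seq_along(sides)) {
    mem <- logical(n)
    mem[sides[[s]]] <- TRUE
    A[, s] <- mem[pr[, 1L]] != mem[pr[, 2L]]
  }
  fit <- pracma::lsqnonneg(A, d[upper.tri(d)])
  as.numeric(fit$x)
}

# greedy dimension filter: drop lowest-weight splits until the
# incompatibility graph has no clique larger than maxDim
dimensionFilter <- function(ss, maxDim = 4) {
  repeat {
    n <- length(ss@taxa)
    k <- length(ss@splits)
    if (k < maxDim + 1) return(ss)
    inc <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      inc[i, j] <- inc[j, i] <-
        !splitsCompatible(ss@splits[[i]], ss@splits[[j]], n)
    if (!any(inc)) return(ss)
    g <- igraph::graph_from_adjacency_matrix(inc, mode = "undirected")
    if (igraph::clique_num(g) <= maxDim) return(ss)
    cand <- unique(unlist(igraph::largest_cliques(g)))
    drop <- cand[which.min(ss@weights[cand])]
    ss <- new("SplitSystem", taxa = ss@taxa, splits = ss@splits[-drop],
              weights = ss@weights[-drop], circularOrder = ss@circularOrder)
  }
}

#' Fit statistics between observed distances and a split system
#'
#' The induced distance `p_ij` is the sum of the weights of the splits
#' separating taxa `i` and `j`. Over unordered pairs,
#' `fit = 100 (1 - sum |d_ij - p_ij| / sum d_ij)` and
#' `LSfit = 100 (1 - sum (d_ij - p_ij)^2 / sum d_ij^2)`. An exact
#' representation gives `fit = LSfit = 100`; the empty split system gives
#' `fit = 0` against any nonzero distances.
#'
#' @param d observed symmetric distance matrix.
#' @param ss a [SplitSystem-class] on the same taxa.
#' @return a list with `fit`, `LSfit` (percent), and the `induced`
#'   distance matrix. All-zero `d` yields `NA` statistics with a warning.
#' @export
fitStatistics <- function(d, ss) {
  d <- validateDistanceMatrix(d)
  if (!setequal(rownames(d), ss@taxa)) stop("taxon sets differ")
  d <- d[ss@taxa, ss@taxa]
  p <- splitDistances(ss)
  up <- upper.tri(d)
  if (sum(d[up]) == 0) {
    warning("all observed distances are zero; fit undefined")
    return(list(fit = NA_real_, LSfit = NA_real_, induced = p))
  }
  list(fit = 100 * (1 - sum(abs(d[up] - p[up])) / sum(d[up])),
       LSfit = 100 * (1 - sum((d[up] - p[up])^2) / sum(d[up]^2)),
       induced = p)
}
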