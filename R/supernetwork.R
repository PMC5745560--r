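#' @include AllClasses.R utils.R
NULL

#' Z-closure supernetwork from partially overlapping trees
#'
#' Builds a split system on the union of the input trees' taxa. Every
#' branch of every input tree contributes a partial split (a bipartition of
#' that tree's taxon set). The Z-closure rule is then applied to pairs of
#' partial splits until no rule fires: for partial splits `A1|B1` and
#' `A2|B2` with `A1` meeting `A2` and `B1` meeting `B2` while `A2` and
#' `B1` are disjoint, the pair is replaced by `(A1 u A2)|B1` and
#' `A2|(B1 u B2)` (applied only when a side strictly grows; both
#' replacements are consistent extensions whenever the two splits
#' restrict a common full split). Because the rule outcome depends on
#' the order in which pairs are inspected, the closure is repeated over
#' `orderings` random pair orders and the completed full splits are pooled.
#'
#' Splits that cover the full taxon set are returned, deduplicated, with
#' weight equal to the mean length of the input branches that produced
#' them (1 when lengths are absent). Taxa whose trivial split did not
#' complete (e.g. taxa connected to the rest only weakly) receive it with
#' the mean of their pendant branch lengths; trees sharing no taxa with
#' the others trigger a warning and contribute trivial splits only.
#'
#' @param trees list of `ape::phylo` trees (or a `multiPhylo`).
#' @param orderings number of random pair orders, default 10.
#' @param seed integer seed making the pooled result reproducible.
#' @return a [SplitSystem-class] (no circular order).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' sn <- zclosureSupernetwork(list(tr), seed = 1)
#' nSplits(sn)   # the tree's own splits
#' @export
zclosureSupernetwork <- function(trees, orderings = 10L, seed = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("at least one input tree is required")
  taxa <- unique(unlist(lapply(trees, function(t) t$tip.label)))
  n <- length(taxa)

  # connectivity over shared taxa
  if (length(trees) > 1L) {
    adj <- matrix(FALSE, length(trees), length(trees))
    for (i in seq_along(trees)) for (j in seq_along(trees))
      adj[i, j] <- i != j &&
        length(intersect(trees[[i]]$tip.label, trees[[j]]$tip.label)) > 0L
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no > 1L)
      warning("input trees do not overlap in a connected sense; ",
              "disconnected taxa get trivial splits only")
  }

  # initial partial splits, one per branch, with provenance
  init <- list()
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    sp <- treeSplits(tr, taxa = taxa, trivial = TRUE)
    hasLen <- !is.null(tr$edge.length)
    tset <- match(tr$tip.label, taxa)
    for (k in seq_along(sp$sides)) {
      A <- intersect(sp$sides[[k]], tset)
      B <- setdiff(tset, A)
      if (!length(A) || !length(B)) next
      init[[length(init) + 1L]] <- list(
        A = sort(A), B = sort(B),
        origin = sprintf("%d.%d", ti, k),
        w = if (hasLen) sp$weights[k] else 1)
    }
  }

  full <- new.env(parent = emptyenv())   # key -> list(origins, weights)
  addFull <- function(side, origin, w) {
    key <- splitKey(canonicalSide(side, n))
    cur <- full[[key]]
    if (is.null(cur)) cur <- list(origins = character(), w = numeric())
    if (!origin %in% cur$origins) {
      cur$origins <- c(cur$origins, origin)
      cur$w <- c(cur$w, w)
    }
    full[[key]] <- cur
  }

  useMask <- n <= 30L
  if (useMask) {
    A0 <- vapply(init, function(s) sum(bitwShiftL(1L, s$A - 1L)), 0L)
    B0 <- vapply(init, function(s) sum(bitwShiftL(1L, s$B - 1L)), 0L)
    fullMask <- sum(bitwShiftL(1L, seq_len(n) - 1L))
  }
  m <- length(init)
  pairIdx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  withSeed(seed, {
    for (run in seq_len(max(1L, orderings))) {
      if (useMask) {
        A <- A0; B <- B0
        repeat {
          ord <- sample.int(nrow(pairIdx))
          fired <- FALSE
          for (p in ord) {
            i <- pairIdx[p, 1L]; j <- pairIdx[p, 2L]
            z <- zRuleMask(A[i], B[i], A[j], B[j])
            if (!is.null(z)) {
              A[i] <- z[1L]; B[i] <- z[2L]
              A[j] <- z[3L]; B[j] <- z[4L]
              fired <- TRUE
            }
          }
          if (!fired) break
        }
        done <- bitwOr(A, B) == fullMask
        for (i in which(done))
          addFull(which(bitwAnd(A[i], bitwShiftL(1L, seq_len(n) - 1L)) != 0L),
                  init[[i]]$origin, init[[i]]$w)
      } else {
        ps <- init
        repeat {
          ord <- sample.int(nrow(pairIdx))
          fired <- FALSE
          for (p in ord) {
            i <- pairIdx[p, 1L]; j <- pairIdx[p, 2L]
            z <- zRule(ps[[i]], ps[[j]])
            if (!is.null(z)) {
              ps[[i]] <- z[[1L]]; ps[[j]] <- z[[2L]]
              fired <- TRUE
            }
          }
          if (!fired) break
        }
        for (s in ps)
          if (length(s$A) + length(s$B) == n) addFull(s$A, s$origin, s$w)
      }
    }
  })

  keys <- ls(full)
  sides <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1L]]))
  weights <- vapply(keys, function(k) mean(full[[k]]$w), 0)

  # guarantee trivial splits for every taxon
  have <- vapply(sides, splitKey, "")
  for (i in seq_len(n)) {
    s <- canonicalSide(i, n)
    if (!splitKey(s) %in% have) {
      pend <- unlist(lapply(trees, pendantLength, label = taxa[i]))
      sides <- c(sides, list(s))
      weights <- c(weights, if (length(pend)) mean(pend) else 1)
    }
  }
  splitSystem(taxa, sides, weights)
}

# bitmask form of the Z-closure rule (taxon sets as bit masks); tries all
# role orders and side flips, returns the updated c(a1', b1', a2', b2')
# or NULL when no orientation fires with strict growth
zRuleMask <- function(a1, b1, a2, b2) {
  sides <- list(c(a1, b1), c(a2, b2))
  for (p in 1:2) {
    q <- 3L - p
    for (f1 in 0:1) for (f2 in 0:1) {
      A1 <- sides[[p]][1L + f1]; B1 <- sides[[p]][2L - f1]
      A2 <- sides[[q]][1L + f2]; B2 <- sides[[q]][2L - f2]
      if (bitwAnd(A1, A2) != 0L && bitwAnd(B1, B2) != 0L &&
          bitwAnd(A2, B1) == 0L) {
        nA1 <- bitwOr(A1, A2); nB2 <- bitwOr(B1, B2)
        if (nA1 != A1 || nB2 != B2) {
          sides[[p]][1L + f1] <- nA1
          sides[[q]][2L - f2] <- nB2
          return(c(sides[[1L]], sides[[2L]]))
        }
      }
    }
  }
  NULL
}

# apply the Z-closure rule to an ordered pair of partial splits; returns
# NULL when no orientation fires with strict growth
zRule <- function(s1, s2) {
  orient <- list(c(1L, 2L), c(2L, 1L))
  for (o in orient) {
    a <- list(s1, s2)[[o[1L]]]
    b <- list(s1, s2)[[o[2L]]]
    for (swapA in c(FALSE, TRUE)) for (swapB in c(FALSE, TRUE)) {
      A1 <- if (swapA) a$B else a$A
      B1 <- if (swapA) a$A else a$B
      A2 <- if (swapB) b$B else b$A
      B2 <- if (swapB) b$A else b$B
      if (length(intersect(A1, A2)) && length(intersect(B1, B2)) &&
          !length(intersect(A2, B1))) {
        newA1 <- sort(union(A1, A2))
        newB2 <- sort(union(B1, B2))
        if (length(newA1) > length(A1) || length(newB2) > length(B2)) {
          na <- a; nb <- b
          if (swapA) na$B <- newA1 else na$A <- newA1
          if (swapB) nb$A <- newB2 else nb$B <- newB2
          res <- list()
          res[[o[1L]]] <- na
          res[[o[2L]]] <- nb
          return(res)
        }
      }
    }
  }
  NULL
}

# pendant branch length of a labelled tip (numeric(0) if absent/no lengths)
pendantLength <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (is.na(i) || is.null(tree$edge.length)) return(numeric())
  tree$edge.length[tree$edge[, 2L] == i]
}
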