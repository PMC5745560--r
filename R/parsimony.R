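#' @include AllClasses.R utils.R mixed-matrix.R
NULL

BIGCOST <- 1e9

## ---- tree plumbing --------------------------------------------------------

# adjacency/postorder bookkeeping for an edge matrix (2 columns of node
# ids; leaves are ids 1..nLeaves)
rootedOrder <- function(edges, root) {
  nn <- max(edges)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(nn)
  children <- vector("list", nn)
  stack <- root
  parent[root] <- 0L
  visit <- integer()
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    for (w in adj[[v]]) if (w != parent[v]) {
      parent[w] <- v
      children[[v]] <- c(children[[v]], w)
      stack <- c(stack, w)
    }
  }
  list(post = rev(visit), children = children, parent = parent)
}

# unrooted edge matrix of an ape::phylo, with leaves renumbered to match
# `taxa`; returns list(edges, leafTaxon) where leafTaxon maps node id ->
# taxon name
phyloToEdges <- function(tree, taxa) {
  nt <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, taxa)
  if (length(miss))
    stop("tree leaf without matrix row: ", paste(miss, collapse = ", "))
  edges <- tree$edge
  list(edges = edges, leafTaxon = tree$tip.label, nLeaves = nt)
}

# serialize an edge-matrix tree (leaves = taxon indices) to newick
edgesToNewick <- function(edges, taxa) {
  ro <- rootedOrder(edges, max(edges))
  build <- function(v) {
    ch <- ro$children[[v]]
    if (!length(ch)) return(taxa[v])
    sprintf("(%s)", paste(vapply(ch, build, ""), collapse = ","))
  }
  paste0(build(max(edges)), ";")
}

edgesToPhylo <- function(edges, taxa) {
  ape::read.tree(text = edgesToNewick(edges, taxa))
}

## ---- scoring engines ------------------------------------------------------

# Sankoff-style uniform-cost optimization of one discrete partition on a
# rooted node ordering; exact on arbitrary (also multifurcating) trees.
# leafState: taxa x chars character matrix; states outside `alphabet` and
# "?" are missing. Returns per-character minimum steps.
scoreDiscrete <- function(ro, leafTaxon, leafState, alphabet) {
  k <- length(alphabet)
  nchar <- ncol(leafState)
  if (!nchar) return(numeric(0))
  cost <- vector("list", length(ro$post))
  names(cost) <- as.character(ro$post)
  C <- vector("list", max(ro$post))
  for (v in ro$post) {
    ch <- ro$children[[v]]
    if (!length(ch)) {
      st <- leafState[leafTaxon[v], ]
      m <- matrix(BIGCOST, k, nchar)
      known <- st %in% alphabet
      if (any(known))
        m[cbind(match(st[known], alphabet), which(known))] <- 0
      m[, !known] <- 0
      C[[v]] <- m
    } else {
      m <- matrix(0, k, nchar)
      for (w in ch) {
        cw <- C[[w]]
        low <- apply(cw, 2L, min)
        m <- m + pmin(cw, rep(low + 1, each = k))
        C[w] <- list(NULL)
      }
      C[[v]] <- m
    }
  }
  apply(C[[ro$post[length(ro$post)]]], 2L, min)
}

# Farris interval (L1) optimization of a continuous partition; envelopes
# are V-shaped (interval bottom + unit arms) which is closed under the
# combine-and-smooth recursion, so the result is exact on arbitrary trees.
# Returns per-character minimum total change on the standardized scale.
scoreContinuous <- function(ro, leafTaxon, leafValue) {
  nchar <- ncol(leafValue)
  if (!nchar) return(numeric(0))
  LO <- vector("list", max(ro$post))
  HI <- vector("list", max(ro$post))
  CO <- vector("list", max(ro$post))
  for (v in ro$post) {
    ch <- ro$children[[v]]
    if (!length(ch)) {
      x <- leafValue[leafTaxon[v], ]
      lo <- ifelse(is.na(x), -Inf, x)
      hi <- ifelse(is.na(x), Inf, x)
      LO[[v]] <- lo; HI[[v]] <- hi; CO[[v]] <- numeric(nchar)
    } else if (length(ch) == 2L) {
      l1 <- LO[[ch[1L]]]; h1 <- HI[[ch[1L]]]
      l2 <- LO[[ch[2L]]]; h2 <- HI[[ch[2L]]]
      ilo <- pmax(l1, l2); ihi <- pmin(h1, h2)
      gap <- pmax(0, ilo - ihi)
      LO[[v]] <- pmin(ilo, ihi)
      HI[[v]] <- pmax(ilo, ihi)
      CO[[v]] <- CO[[ch[1L]]] + CO[[ch[2L]]] + gap
    } else {
      lo <- hi <- co <- numeric(nchar)
      for (j in seq_len(nchar)) {
        ints <- cbind(lo = vapply(ch, function(w) LO[[w]][j], 0),
                      hi = vapply(ch, function(w) HI[[w]][j], 0))
        base <- sum(vapply(ch, function(w) CO[[w]][j], 0))
        cand <- unique(c(ints[is.finite(ints[, 1L]), 1L],
                         ints[is.finite(ints[, 2L]), 2L]))
        if (!length(cand)) {
          lo[j] <- -Inf; hi[j] <- Inf; co[j] <- base
        } else {
          f <- vapply(cand, function(v0)
            sum(pmax(0, ints[, 1L] - v0, v0 - ints[, 2L])), 0)
          m <- min(f)
          lo[j] <- min(cand[f <= m + 1e-12])
          hi[j] <- max(cand[f <= m + 1e-12])
          co[j] <- base + m
        }
      }
      LO[[v]] <- lo; HI[[v]] <- hi; CO[[v]] <- co
    }
  }
  CO[[ro$post[length(ro$post)]]]
}

## fast search path: precomputed scoring context ---------------------------

# precompute per-partition leaf encodings; rows indexed by taxon position
# in mm@taxa. Discrete states become bitmasks (missing = full mask) so
# binary trees can be scored by vectorized Fitch operations.
prepareScoring <- function(mm) {
  parts <- list()
  for (p in mm@partitions) {
    if (!ncol(p@data)) next
    if (p@ctype == "continuous") {
      lo <- p@data; hi <- p@data
      lo[!is.finite(lo)] <- -Inf
      hi[!is.finite(hi)] <- Inf
      parts[[length(parts) + 1L]] <-
        list(type = "cont", lo = unname(lo), hi = unname(hi),
             nchar = ncol(p@data))
    } else {
      alpha <- partitionAlphabet(p)
      k <- length(alpha)
      if (!k) next
      code <- matrix(match(p@data, alpha), nrow(p@data))
      mask <- matrix(bitwShiftL(1L, code - 1L), nrow(code))
      mask[is.na(mask)] <- bitwShiftL(1L, k) - 1L
      parts[[length(parts) + 1L]] <-
        list(type = "disc", mask = mask, nchar = ncol(p@data))
    }
  }
  nchars <- vapply(parts, `[[`, 0L, "nchar")
  list(parts = parts, n = length(mm@taxa), nchar = sum(nchars))
}

# subset the context's character columns (units over the concatenation,
# duplicates allowed)
ctxSubset <- function(ctx, units) {
  widths <- vapply(ctx$parts, `[[`, 0L, "nchar")
  offs <- cumsum(c(0L, widths[-length(widths)]))
  parts <- list()
  for (k in seq_along(ctx$parts)) {
    local <- units[units > offs[k] & units <= offs[k] + widths[k]] - offs[k]
    if (!length(local)) next
    p <- ctx$parts[[k]]
    if (p$type == "cont") {
      p$lo <- p$lo[, local, drop = FALSE]
      p$hi <- p$hi[, local, drop = FALSE]
    } else p$mask <- p$mask[, local, drop = FALSE]
    p$nchar <- length(local)
    parts[[length(parts) + 1L]] <- p
  }
  list(parts = parts, n = ctx$n,
       nchar = sum(vapply(parts, `[[`, 0L, "nchar")))
}

# total parsimony score of an edge-matrix tree (leaves = taxon indices)
# against a prepared context; exact for binary trees with at most one
# multifurcation folded sequentially at the root (the representation the
# search generates)
scoreCtx <- function(edges, ctx) {
  ro <- rootedOrder(edges, max(edges))
  total <- 0
  for (p in ctx$parts) {
    if (p$type == "disc") {
      M <- vector("list", max(edges))
      steps <- 0L
      for (v in ro$post) {
        ch <- ro$children[[v]]
        if (!length(ch)) { M[[v]] <- p$mask[v, ]; next }
        m <- M[[ch[1L]]]
        for (w in ch[-1L]) {
          a <- bitwAnd(m, M[[w]])
          z <- a == 0L
          if (any(z)) {
            a[z] <- bitwOr(m[z], M[[w]][z])
            steps <- steps + sum(z)
          }
          m <- a
        }
        M[[v]] <- m
      }
      total <- total + steps
    } else {
      LO <- vector("list", max(edges))
      HI <- vector("list", max(edges))
      cost <- 0
      for (v in ro$post) {
        ch <- ro$children[[v]]
        if (!length(ch)) { LO[[v]] <- p$lo[v, ]; HI[[v]] <- p$hi[v, ]; next }
        l1 <- LO[[ch[1L]]]; h1 <- HI[[ch[1L]]]
        for (w in ch[-1L]) {
          ilo <- pmax(l1, LO[[w]]); ihi <- pmin(h1, HI[[w]])
          gap <- ilo - ihi
          over <- gap > 0
          if (any(over)) {
            cost <- cost + sum(gap[over])
            tmp <- ilo[over]; ilo[over] <- ihi[over]; ihi[over] <- tmp
          }
          l1 <- ilo; h1 <- ihi
        }
        LO[[v]] <- l1; HI[[v]] <- h1
      }
      total <- total + cost
    }
  }
  total
}

# per-character steps of a mixed matrix on an edge-matrix tree
scoreEdges <- function(edges, leafTaxon, mm) {
  ro <- rootedOrder(edges, max(edges))
  steps <- numeric()
  for (p in mm@partitions) {
    if (!ncol(p@data)) next
    s <- if (p@ctype == "continuous")
      scoreContinuous(ro, leafTaxon, p@data)
    else scoreDiscrete(ro, leafTaxon, p@data, partitionAlphabet(p))
    steps <- c(steps, s)
  }
  steps
}

#' Parsimony length of a tree under a mixed character matrix
#'
#' Discrete partitions (DNA with optional gap-as-fifth-state, binary,
#' unordered multistate) are scored by uniform-cost Fitch optimization,
#' exact also on multifurcating trees; continuous partitions by Farris
#' interval (L1) optimization on the range-standardized scale. Missing
#' entries (`?`/`NA`) force no steps. The total is the equally weighted
#' sum over all characters.
#'
#' @param tree an `ape::phylo`; its leaves must all have matrix rows.
#' @param mm a [MixedMatrix-class].
#' @param perCharacter return the per-character step vector instead of
#'   the total?
#' @return numeric: the tree length (or per-character steps).
#' @export
treeLength <- function(tree, mm, perCharacter = FALSE) {
  pe <- phyloToEdges(tree, mm@taxa)
  steps <- scoreEdges(pe$edges, pe$leafTaxon, mm)
  if (perCharacter) steps else sum(steps)
}

## ---- character bounds, CI, RI --------------------------------------------

# per-character minimum and maximum possible steps (maximum = star-tree
# length: discrete n_obs - max state frequency; continuous
# sum |x - median|)
characterBounds <- function(mm) {
  mins <- numeric(); maxs <- numeric()
  for (p in mm@partitions) {
    if (!ncol(p@data)) next
    if (p@ctype == "continuous") {
      for (j in seq_len(ncol(p@data))) {
        x <- p@data[, j]
        x <- x[is.finite(x)]
        if (length(x) < 2L) { mins <- c(mins, 0); maxs <- c(maxs, 0); next }
        mins <- c(mins, diff(range(x)))
        maxs <- c(maxs, sum(abs(x - stats::median(x))))
      }
    } else {
      alpha <- partitionAlphabet(p)
      for (j in seq_len(ncol(p@data))) {
        st <- p@data[, j]
        st <- st[st %in% alpha]
        if (length(st) < 2L || length(unique(st)) < 2L) {
          mins <- c(mins, 0); maxs <- c(maxs, 0); next
        }
        tab <- table(st)
        mins <- c(mins, length(tab) - 1L)
        maxs <- c(maxs, length(st) - max(tab))
      }
    }
  }
  list(min = mins, max = maxs)
}

consistencyIndices <- function(mm, score) {
  b <- characterBounds(mm)
  ci <- if (score > 0) sum(b$min) / score else NA_real_
  denom <- sum(b$max) - sum(b$min)
  ri <- if (denom > 0) (sum(b$max) - score) / denom else NA_real_
  list(CI = ci, RI = ri, minSteps = sum(b$min), maxSteps = sum(b$max))
}

## ---- exact search ---------------------------------------------------------

# crude pairwise dissimilarity used only for the taxon-addition order
mixedDistance <- function(mm) {
  n <- length(mm@taxa)
  d <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (p in mm@partitions) {
    if (!ncol(p@data)) next
    if (p@ctype == "continuous") {
      for (j in seq_len(ncol(p@data))) {
        x <- p@data[, j]
        ok <- is.finite(x)
        dd <- abs(outer(x, x, "-"))
        dd[!ok, ] <- 0; dd[, !ok] <- 0
        d <- d + dd
        cnt <- cnt + outer(ok, ok, "&")
      }
    } else {
      alpha <- partitionAlphabet(p)
      for (j in seq_len(ncol(p@data))) {
        st <- p@data[, j]
        ok <- st %in% alpha
        dd <- outer(st, st, "!=") * 1
        dd[!ok, ] <- 0; dd[, !ok] <- 0
        d <- d + dd
        cnt <- cnt + outer(ok, ok, "&")
      }
    }
  }
  d / pmax(cnt, 1)
}

# max-min distance taxon-addition order, ties broken by smallest index
additionOrder <- function(mm) {
  d <- mixedDistance(mm)
  n <- nrow(d)
  diag(d) <- -Inf   # never pair a taxon with itself (all-zero matrices)
  first <- arrayInd(which.max(d), dim(d))[1L, ]
  diag(d) <- 0
  sel <- sort(unique(first))
  if (length(sel) < 2L) sel <- 1:2
  while (length(sel) < n) {
    rest <- setdiff(seq_len(n), sel)
    mins <- vapply(rest, function(i) min(d[i, sel]), 0)
    sel <- c(sel, rest[which.max(mins)])
  }
  sel
}

insertLeaf <- function(edges, e, leaf, newNode) {
  u <- edges[e, 1L]; v <- edges[e, 2L]
  rbind(edges[-e, , drop = FALSE],
        c(u, newNode), c(newNode, v), c(newNode, leaf))
}

#' Exact maximum-parsimony search by branch and bound
#'
#' Finds all most-parsimonious unrooted trees for a mixed matrix.
#' Taxa are added in max-min distance order; partial-tree scores are
#' valid lower bounds, and a greedy-addition tree provides the initial
#' upper bound. The search is exact and is refused above `maxTaxa` (the
#' tool targets the small taxon sets of total-evidence studies; heuristic
#' search is out of scope).
#'
#' @param mm a [MixedMatrix-class].
#' @param maxTaxa refuse matrices with more taxa than this (default 14).
#' @return a list of class `"parsimonyResult"`: `trees` (`multiPhylo` of
#'   all MP trees), `score`, `CI`, `RI`, `minSteps`, `maxSteps`,
#'   `consensusSides` (splits shared by every MP tree, as canonical taxon
#'   index sets), and `degenerate` (TRUE when every character is
#'   uninformative and all topologies tie at score 0; `CI` is then `NA`).
#' @export
exactSearch <- function(mm, maxTaxa = 14L) {
  n <- length(mm@taxa)
  if (n > maxTaxa)
    stop(sprintf(paste0("exact search is limited to %d taxa (%d given); ",
                        "reduce the taxon set or analyse a subset"),
                 maxTaxa, n))
  if (n < 3L) stop("at least 3 taxa are required")
  ctx <- prepareScoring(mm)
  core <- searchCore(ctx, additionOrder(mm))
  finishSearch(core$found, core$best, mm, mm@taxa)
}

# branch-and-bound over the prepared context; returns the MP edge
# matrices and score
searchCore <- function(ctx, ord = seq_len(ctx$n)) {
  n <- ctx$n
  if (n == 3L) {
    edges <- cbind(4L, 1:3)
    storage.mode(edges) <- "integer"
    return(list(found = list(edges), best = scoreCtx(edges, ctx)))
  }
  base <- cbind(n + 1L, ord[1:3])
  storage.mode(base) <- "integer"

  # greedy-addition upper bound
  gEdges <- base
  for (i in 4:n) {
    bestS <- Inf; bestE <- NULL
    for (e in seq_len(nrow(gEdges))) {
      cand <- insertLeaf(gEdges, e, ord[i], n + i - 2L)
      s <- scoreCtx(cand, ctx)
      if (s < bestS) { bestS <- s; bestE <- cand }
    }
    gEdges <- bestE
  }
  best <- scoreCtx(gEdges, ctx)
  found <- list(gEdges)

  recurse <- function(edges, i) {
    for (e in seq_len(nrow(edges))) {
      cand <- insertLeaf(edges, e, ord[i], n + i - 2L)
      s <- scoreCtx(cand, ctx)
      if (s > best) next
      if (i == n) {
        if (s < best) { best <<- s; found <<- list() }
        found[[length(found) + 1L]] <<- cand
      } else {
        recurse(cand, i + 1L)
      }
    }
  }
  recurse(base, 4L)
  # the greedy tree is re-found during the search; finishSearch dedupes
  list(found = found, best = best)
}

# non-trivial split keys of an edge-matrix tree over n leaves
edgeSideKeys <- function(edges, n) {
  root <- max(edges)
  ro <- rootedOrder(edges, root)
  below <- vector("list", root)
  keys <- character()
  for (v in ro$post) {
    ch <- ro$children[[v]]
    below[[v]] <- if (!length(ch)) v else sort(unlist(below[ch]))
    if (v == root) next
    tips <- below[[v]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    keys <- c(keys, splitKey(canonicalSide(tips, n)))
  }
  unique(keys)
}

finishSearch <- function(found, best, mm, leafTaxon) {
  n <- length(leafTaxon)
  sideSets <- lapply(found, edgeSideKeys, n = n)
  topoKey <- vapply(sideSets, function(k) paste(sort(k), collapse = ";"), "")
  keep <- !duplicated(topoKey)
  found <- found[keep]
  sideSets <- sideSets[keep]
  trees <- lapply(found, edgesToPhylo, taxa = leafTaxon)
  class(trees) <- "multiPhylo"
  consensus <- Reduce(intersect, sideSets)
  idx <- consistencyIndices(mm, best)
  structure(list(trees = trees, score = best, CI = idx$CI, RI = idx$RI,
                 minSteps = idx$minSteps, maxSteps = idx$maxSteps,
                 consensusSides = lapply(consensus, function(k)
                   as.integer(strsplit(k, ",")[[1L]])),
                 degenerate = best == 0),
            class = "parsimonyResult")
}

#' @export
print.parsimonyResult <- function(x, ...) {
  cat(sprintf("Exact parsimony search: %d MP tree(s), score %.4f\n",
              length(x$trees), x$score))
  if (x$degenerate)
    cat("  all characters uninformative: every topology ties at 0; CI undefined\n")
  else
    cat(sprintf("  CI = %.3f, RI = %s\n", x$CI,
                if (is.na(x$RI)) "NA" else sprintf("%.3f", x$RI)))
  invisible(x)
}
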