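#' @include AllClasses.R utils.R parsimony.R
NULL

#' Map non-ambiguous synapomorphies on a rooted tree
#'
#' Optimizes every character of a mixed matrix over `tree` rooted by the
#' matrix's dummy outgroup and reports the state changes that occur on the
#' same branch with the same direction in *every* most-parsimonious
#' reconstruction:
#'
#' * discrete characters: all MP reconstructions are enumerated from the
#'   uniform-cost dynamic programme and their change sets intersected
#'   (for a character with a unique reconstruction this reduces to the
#'   ACCTRAN = DELTRAN changes);
#' * continuous characters: a change on a branch is forced when the
#'   optimal-value intervals of the two half-trees separated by the branch
#'   are disjoint; the direction and the minimal forced magnitude (the
#'   interval gap, on the standardized scale) are reported.
#'
#' @param tree an unrooted or rooted `ape::phylo` containing all matrix
#'   taxa including the outgroup (e.g. one of the [exactSearch()] MP
#'   trees).
#' @param mm a [MixedMatrix-class] with a dummy outgroup (needed to
#'   polarize change; an error is raised otherwise).
#' @param enumLimit cap on enumerated reconstructions per character;
#'   characters exceeding it are conservatively treated as ambiguous,
#'   with a message.
#' @return a data.frame of class `"synapomorphyMap"`: `branch` (sorted
#'   comma-joined ingroup clade below the branch), `character`, `ctype`,
#'   `from`, `to`, `direction` (`increase`/`decrease` for continuous),
#'   `magnitude`.
#' @export
mapSynapomorphies <- function(tree, mm, enumLimit = 20000L) {
  if (is.na(mm@outgroup))
    stop("polarization undefined: the matrix has no outgroup ",
         "(assemble it with dummyOutgroup = TRUE)")
  if (!mm@outgroup %in% tree$tip.label)
    stop("tree does not contain the outgroup taxon")
  rt <- ape::root(ape::unroot(tree), outgroup = mm@outgroup,
                  resolve.root = TRUE)
  pe <- phyloToEdges(rt, mm@taxa)
  edges <- pe$edges
  nt <- pe$nLeaves
  root <- nt + 1L
  ro <- rootedOrder(edges, root)
  ogNode <- match(mm@outgroup, rt$tip.label)
  # branch label: sorted clade of leaves below the child node
  desc <- descendantTips(rt)
  branchLabel <- function(child) {
    tips <- if (child <= nt) child else desc[[child]]
    paste(sort(rt$tip.label[tips]), collapse = ",")
  }
  out <- list()
  for (p in mm@partitions) {
    for (j in seq_len(ncol(p@data))) {
      charLab <- sprintf("%s_%d", p@name, j)
      if (p@ctype == "continuous") {
        ch <- continuousForcedChanges(ro, edges, pe$leafTaxon,
                                      p@data[, j, drop = FALSE], root)
        if (nrow(ch)) {
          keep <- ch$child != ogNode
          ch <- ch[keep, , drop = FALSE]
          for (i in seq_len(nrow(ch)))
            out[[length(out) + 1L]] <- data.frame(
              branch = branchLabel(ch$child[i]), character = charLab,
              ctype = "continuous",
              from = format(ch$from[i]), to = format(ch$to[i]),
              direction = ch$direction[i], magnitude = ch$magnitude[i])
        }
      } else {
        uc <- unambiguousDiscreteChanges(ro, pe$leafTaxon,
                                         p@data[, j, drop = FALSE],
                                         partitionAlphabet(p), root,
                                         enumLimit, charLab)
        if (length(uc)) for (chg in uc) {
          if (chg$child == ogNode) next
          out[[length(out) + 1L]] <- data.frame(
            branch = branchLabel(chg$child), character = charLab,
            ctype = p@ctype, from = chg$from, to = chg$to,
            direction = sprintf("%s->%s", chg$from, chg$to),
            magnitude = 1)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(branch = character(), character = character(),
               ctype = character(), from = character(), to = character(),
               direction = character(), magnitude = numeric())
  rownames(res) <- NULL
  class(res) <- c("synapomorphyMap", "data.frame")
  res
}

# enumerate all MP reconstructions of one discrete character and return
# the changes common to every one; each change is list(child, from, to)
unambiguousDiscreteChanges <- function(ro, leafTaxon, col, alphabet, root,
                                       enumLimit, charLab) {
  k <- length(alphabet)
  if (!k) return(list())
  nn <- max(ro$post)
  C <- vector("list", nn)
  for (v in ro$post) {
    chn <- ro$children[[v]]
    if (!length(chn)) {
      st <- col[leafTaxon[v], 1L]
      cv <- rep(BIGCOST, k)
      if (st %in% alphabet) cv[match(st, alphabet)] <- 0 else cv[] <- 0
      C[[v]] <- cv
    } else {
      cv <- rep(0, k)
      for (w in chn) cv <- cv + pmin(C[[w]], min(C[[w]]) + 1)
      C[[v]] <- cv
    }
  }
  tol <- 1e-9
  common <- NULL
  count <- 0L
  truncated <- FALSE
  # depth-first enumeration of optimality-consistent state assignments in
  # preorder; `common` is intersected as reconstructions complete and the
  # walk aborts once it empties
  assign <- integer(nn)
  changes <- character()
  enum <- function(idx) {
    if (truncated) return()
    if (!is.null(common) && !length(common)) return()
    if (idx > length(pre)) {
      count <<- count + 1L
      if (count > enumLimit) { truncated <<- TRUE; return() }
      if (is.null(common)) common <<- changes
      else common <<- intersect(common, changes)
      return()
    }
    v <- pre[idx]
    par <- ro$parent[v]
    if (par == 0L) {
      best <- min(C[[v]])
      for (s in which(C[[v]] <= best + tol)) {
        assign[v] <<- s
        enum(idx + 1L)
      }
    } else {
      sp <- assign[par]
      contrib <- pmin(C[[v]], min(C[[v]]) + 1)
      need <- contrib[sp]
      for (s in seq_len(k)) {
        if (C[[v]][s] + as.numeric(s != sp) <= need + tol) {
          assign[v] <<- s
          added <- s != sp
          if (added)
            changes <<- c(changes,
                          sprintf("%d|%s|%s", v, alphabet[sp], alphabet[s]))
          enum(idx + 1L)
          if (added) changes <<- changes[-length(changes)]
        }
      }
    }
  }
  pre <- rev(ro$post)
  enum(1L)
  if (truncated) {
    message(sprintf("character %s: more than %d MP reconstructions; treated as ambiguous",
                    charLab, enumLimit))
    return(list())
  }
  if (is.null(common) || !length(common)) return(list())
  lapply(common, function(s) {
    parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
    list(child = as.integer(parts[1L]), from = parts[2L], to = parts[3L])
  })
}

# forced changes of one continuous character: for each branch, the gap
# between the optimal-value intervals of the two half-trees it separates
continuousForcedChanges <- function(ro, edges, leafTaxon, col, root) {
  nn <- max(ro$post)
  # up envelopes (subtree below each node)
  upLo <- rep(-Inf, nn); upHi <- rep(Inf, nn); upCo <- numeric(nn)
  for (v in ro$post) {
    chn <- ro$children[[v]]
    if (!length(chn)) {
      x <- col[leafTaxon[v], 1L]
      if (is.finite(x)) { upLo[v] <- x; upHi[v] <- x }
    } else {
      env <- envSum(upLo[chn], upHi[chn], upCo[chn])
      upLo[v] <- env$lo; upHi[v] <- env$hi; upCo[v] <- env$cost
    }
  }
  # down envelopes (rest of tree, seen from each node's parent side)
  dnLo <- rep(-Inf, nn); dnHi <- rep(Inf, nn); dnCo <- numeric(nn)
  for (v in rev(ro$post)) {          # preorder
    chn <- ro$children[[v]]
    if (!length(chn)) next
    for (w in chn) {
      sib <- setdiff(chn, w)
      lo <- upLo[sib]; hi <- upHi[sib]; co <- upCo[sib]
      if (ro$parent[v] != 0L) {
        lo <- c(lo, dnLo[v]); hi <- c(hi, dnHi[v]); co <- c(co, dnCo[v])
      }
      if (!length(lo)) { dnLo[w] <- -Inf; dnHi[w] <- Inf; dnCo[w] <- 0 }
      else {
        env <- envSum(lo, hi, co)
        dnLo[w] <- env$lo; dnHi[w] <- env$hi; dnCo[w] <- env$cost
      }
    }
  }
  out <- list()
  for (v in ro$post) {
    if (ro$parent[v] == 0L) next
    gapUp <- dnHi[v] < upLo[v]    # subtree values forced above the rest
    gapDn <- upHi[v] < dnLo[v]
    if (is.finite(upLo[v]) || is.finite(upHi[v])) {
      if (isTRUE(gapUp) && upLo[v] - dnHi[v] > 1e-9)
        out[[length(out) + 1L]] <- data.frame(
          child = v, from = dnHi[v], to = upLo[v], direction = "increase",
          magnitude = upLo[v] - dnHi[v])
      else if (isTRUE(gapDn) && dnLo[v] - upHi[v] > 1e-9)
        out[[length(out) + 1L]] <- data.frame(
          child = v, from = dnLo[v], to = upHi[v], direction = "decrease",
          magnitude = dnLo[v] - upHi[v])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(child = integer(), from = numeric(), to = numeric(),
               direction = character(), magnitude = numeric())
}

# bottom interval and minimum of a sum of V-envelopes
envSum <- function(lo, hi, cost) {
  base <- sum(cost)
  cand <- unique(c(lo[is.finite(lo)], hi[is.finite(hi)]))
  if (!length(cand)) return(list(lo = -Inf, hi = Inf, cost = base))
  f <- vapply(cand, function(v) sum(pmax(0, lo - v, v - hi)), 0)
  m <- min(f)
  list(lo = min(cand[f <= m + 1e-12]), hi = max(cand[f <= m + 1e-12]),
       cost = base + m)
}
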