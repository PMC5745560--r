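# shared fixture builders and independent brute-force oracles

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a tiny two-gene genome: geneA = [1,100], geneB = [151,300]
twoGeneGenome <- function(seed = 1) {
  annotatedGenome("toy", randomDna(400, seed), circular = FALSE,
    features = S4Vectors::DataFrame(
      name = c("geneA", "geneB"), kind = "gene", strand = 1L,
      exons = IRanges::IRangesList(IRanges::IRanges(1, 100),
                                   IRanges::IRanges(151, 300))))
}

# brute-force parsimony for one discrete character: enumerate every state
# assignment of internal nodes (and of missing leaves) and count edge
# changes
bruteFitch <- function(tree, states, alphabet) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  fixed <- rep(NA_integer_, nn)
  for (i in seq_len(nt)) {
    s <- states[tree$tip.label[i]]
    if (s %in% alphabet) fixed[i] <- match(s, alphabet)
  }
  free <- which(is.na(fixed))
  k <- length(alphabet)
  best <- Inf
  grid <- rep(1L, length(free))
  repeat {
    asg <- fixed
    asg[free] <- grid
    steps <- sum(asg[tree$edge[, 1L]] != asg[tree$edge[, 2L]])
    best <- min(best, steps)
    i <- 1L
    while (i <= length(grid) && grid[i] == k) { grid[i] <- 1L; i <- i + 1L }
    if (i > length(grid)) break
    grid[i] <- grid[i] + 1L
  }
  best
}

# brute-force L1 (Farris) parsimony for one continuous character:
# optimal internal values can be taken among the observed leaf values
bruteFarris <- function(tree, values) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  obs <- values[tree$tip.label]
  cand <- sort(unique(obs[is.finite(obs)]))
  internals <- (nt + 1L):nn
  best <- Inf
  grid <- rep(1L, length(internals))
  repeat {
    val <- c(obs, cand[grid])[order(c(seq_len(nt), internals))]
    val <- numeric(nn)
    val[seq_len(nt)] <- obs
    val[internals] <- cand[grid]
    dif <- abs(val[tree$edge[, 1L]] - val[tree$edge[, 2L]])
    dif[!is.finite(dif)] <- 0   # missing leaves cost nothing
    best <- min(best, sum(dif))
    i <- 1L
    while (i <= length(grid) && grid[i] == length(cand)) {
      grid[i] <- 1L; i <- i + 1L
    }
    if (i > length(grid)) break
    grid[i] <- grid[i] + 1L
  }
  best
}

# independent double-loop average pairwise p-distance
bruteMeanP <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  tot <- 0; np <- 0L
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
    comp <- ok[i, ] & ok[j, ]
    tot <- tot + sum(m[i, comp] != m[j, comp]) / sum(comp)
    np <- np + 1L
  }
  tot / np
}

# binary character matrix from a MixedMatrix for phangorn cross-checks
asPhyDat <- function(mm) {
  stopifnot(length(mm@partitions) == 1L)
  phangorn::phyDat(mm@partitions[[1L]]@data, type = "USER",
                   levels = c("0", "1"))
}
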