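#' @importFrom Biostrings reverseComplement subseq
#' @importFrom stats runif
NULL

# Evaluate `expr` under a local RNG stream: the global .Random.seed is
# restored afterwards, so generators are pure functions of their seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

# reverse complement of a plain character DNA string (keeps N/IUPAC via
# Biostrings)
revcompChar <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# split a sequence string into a character vector of single letters
seqChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]

# alignment (DNAAlignment / XStringSet / character) as a character matrix,
# rows = taxa
alignmentMatrix <- function(aln) {
  if (is(aln, "XStringSet")) {
    s <- as.character(aln)
  } else if (is.character(aln)) {
    s <- aln
  } else stop("cannot interpret alignment of class ", class(aln)[1L])
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  m <- do.call(rbind, strsplit(toupper(s), "", fixed = TRUE))
  rownames(m) <- names(s)
  m
}

isACGT <- function(m) m == "A" | m == "C" | m == "G" | m == "T"

## ---- split bookkeeping ----------------------------------------------------

# canonical key of an integer split side
splitKey <- function(side) paste(side, collapse = ",")

# canonicalize a side (indices) against n taxa: side not containing taxon 1
canonicalSide <- function(side, n) {
  side <- sort(unique(as.integer(side)))
  if (1L %in% side) side <- setdiff(seq_len(n), side)
  side
}

# are two full splits of the same taxon set compatible?
# (one of the four side intersections is empty)
splitsCompatible <- function(a, b, n) {
  all <- seq_len(n)
  ac <- setdiff(all, a); bc <- setdiff(all, b)
  length(intersect(a, b)) == 0L || length(intersect(a, bc)) == 0L ||
    length(intersect(ac, b)) == 0L || length(intersect(ac, bc)) == 0L
}

# non-trivial splits of an ape::phylo tree, as canonical sides over `taxa`
# (labels defaulting to the tree's own tips); returns list(sides, weights)
treeSplits <- function(tree, taxa = tree$tip.label, trivial = FALSE) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree contains tips absent from the taxon set")
  n <- length(taxa)
  sides <- list(); weights <- numeric()
  desc <- descendantTips(tree)
  edge <- tree$edge
  el <- tree$edge.length
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2L]
    tips <- if (child <= nt) child else desc[[child]]
    if (!trivial && (length(tips) <= 1L || length(tips) >= nt - 1L)) next
    if (trivial && (length(tips) < 1L || length(tips) >= nt)) next
    sides[[length(sides) + 1L]] <- canonicalSide(idx[tips], n)
    weights <- c(weights, if (is.null(el)) 1 else el[e])
  }
  keys <- vapply(sides, splitKey, "")
  keep <- !duplicated(keys)
  list(sides = sides[keep], weights = weights[keep])
}

# tip indices below each internal node of a phylo tree
descendantTips <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  # postorder over edges: children before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1L]; ch <- ord[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# distances induced by a split system: p_ij = sum of weights of splits
# separating i and j; returns an n x n symmetric matrix
splitDistances <- function(ss) {
  n <- length(ss@taxa)
  p <- matrix(0, n, n, dimnames = list(ss@taxa, ss@taxa))
  for (k in seq_along(ss@splits)) {
    side <- ss@splits[[k]]
    other <- setdiff(seq_len(n), side)
    p[side, other] <- p[side, other] + ss@weights[k]
    p[other, side] <- p[other, side] + ss@weights[k]
  }
  p
}
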