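test_that("p-distance matrix follows the pairwise deletion rule", {
  aln <- dnaAlignment(c(a = "ACGTACGT", b = "ACGTACGT",
                        c = "AAGTACGA", d = "ACGTACGT"))
  d <- pDistanceMatrix(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2 / 8)
  # agrees with the marker-selection pairwise machinery
  expect_equal(mean(d[upper.tri(d)]), locusStats(aln)$pBar)
  # pair with zero comparable sites errors naming the pair
  bad <- dnaAlignment(c(a = "AANN", b = "NNAA", c = "ACGT", d = "ACGT"))
  expect_error(pDistanceMatrix(bad), "'a' and 'b'")
})

test_that("Neighbour-Net reproduces a 4-taxon tree metric exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  d <- ape::cophenetic.phylo(tr)
  nn <- neighborNet(d)
  expect_equal(nSplits(nn), 5L)
  key <- vapply(splitSides(nn), function(s) paste(sort(taxonNames(nn)[s]),
                                                  collapse = ","), "")
  w <- setNames(splitWeights(nn), key)
  expect_equal(w[["B"]], 2, tolerance = 1e-8)
  expect_equal(w[["C"]], 3, tolerance = 1e-8)
  expect_equal(w[["D"]], 4, tolerance = 1e-8)
  expect_equal(w[["B,C,D"]], 1, tolerance = 1e-8)   # trivial split of A
  expect_equal(w[["C,D"]], 3, tolerance = 1e-8)     # AB|CD internal path
})

test_that("a star metric yields only trivial splits", {
  n <- 5
  d <- matrix(2, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  diag(d) <- 0
  nn <- neighborNet(d)
  expect_equal(nSplits(nn), n)
  expect_true(all(lengths(splitSides(nn)) %in% c(1L, n - 1L)))
  expect_equal(sort(splitWeights(nn)), rep(1, n), tolerance = 1e-8)
})

test_that("a symmetric four-point violation produces an incompatibility box", {
  taxa <- c("A", "B", "C", "D")
  # AB|CD and AC|BD signals of equal strength
  d <- matrix(c(0, 2, 2, 3,
                2, 0, 3, 2,
                2, 3, 0, 2,
                3, 2, 2, 0), 4, 4, dimnames = list(taxa, taxa))
  nn <- neighborNet(d)
  sides <- vapply(splitSides(nn), function(s)
    paste(sort(taxa[s]), collapse = ","), "")
  nontrivial <- sides[lengths(splitSides(nn)) == 2L]
  expect_equal(length(nontrivial), 2L)
  expect_true(all(splitWeights(nn)[lengths(splitSides(nn)) == 2L] > 0))
  # the two quartet splits conflict: verified against an independent
  # implementation of the same algorithm
  ref <- phangorn::neighborNet(d)
  refSides <- phangorn::as.splits(ref)
  refLab <- attr(refSides, "labels")
  refKeys <- vapply(refSides, function(s) {
    s <- sort(refLab[s])
    if ("A" %in% s) s <- sort(setdiff(taxa, s))
    paste(s, collapse = ",")
  }, "")
  nnKeys <- vapply(splitSides(nn), function(s) paste(sort(taxa[s]),
                                                     collapse = ","), "")
  expect_setequal(setdiff(nnKeys, ""), setdiff(unique(refKeys), ""))
})

test_that("Neighbour-Net recovers random tree metrics exactly", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    nn <- neighborNet(d)
    expect_equal(nSplits(nn), 2 * n - 3)
    # split set equality with the tree, weights = branch lengths
    ts <- plastophylo:::treeSplits(ape::unroot(tr), taxa = rownames(d),
                                   trivial = TRUE)
    trueKeys <- vapply(ts$sides, plastophylo:::splitKey, "")
    nnKeys <- vapply(splitSides(nn), plastophylo:::splitKey, "")
    expect_setequal(nnKeys, trueKeys)
    expect_equal(splitWeights(nn)[match(trueKeys, nnKeys)], ts$weights,
                 tolerance = 1e-6)
    fs <- fitStatistics(d, nn)
    expect_equal(fs$fit, 100, tolerance = 1e-6)
    expect_equal(fs$LSfit, 100, tolerance = 1e-6)
    expect_true(all(splitWeights(nn) >= 0))
  }
})

test_that("every retained split is an interval of the circular ordering", {
  set.seed(55)
  m <- matrix(runif(8 * 8), 8, 8)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("t", 1:8), paste0("t", 1:8))
  nn <- neighborNet(d)
  expect_true(length(circularOrder(nn)) == 8L)
  expect_true(validObject(nn))   # validity asserts the interval property
  pos <- integer(8); pos[circularOrder(nn)] <- 1:8
  for (s in splitSides(nn))
    expect_true(plastophylo:::.isCircularInterval(pos[s], 8))
})

test_that("relaxing the dimension filter never decreases LSfit", {
  set.seed(77)
  for (i in 1:3) {
    m <- matrix(runif(7 * 7), 7, 7)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:7), paste0("t", 1:7))
    filt <- neighborNet(d, maxDim = 2)
    open <- neighborNet(d, maxDim = Inf)
    expect_gte(fitStatistics(d, open)$LSfit + 1e-9,
               fitStatistics(d, filt)$LSfit)
  }
})

test_that("non-symmetric or negative distances are rejected", {
  d <- matrix(c(0, 1, 2, 1, 1, 0, 1, 1, 2, 1, 0, 1, 1, 2, 1, 0), 4, 4)
  expect_error(neighborNet(d), "symmetric")
  d2 <- matrix(0, 4, 4); d2[1, 2] <- d2[2, 1] <- -1
  expect_error(neighborNet(d2), "nonnegative|negative")
})

test_that("fit statistics match hand evaluation of the two formulas", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- ape::cophenetic.phylo(tr)
  nn <- neighborNet(d)
  fs <- fitStatistics(d, nn)
  expect_equal(fs$fit, 100)
  expect_equal(fs$LSfit, 100)
  # drop the internal split: every cross pair loses weight 1
  keep <- lengths(splitSides(nn)) %in% c(1L, 3L)
  ss <- splitSystem(taxonNames(nn), splitSides(nn)[keep],
                    splitWeights(nn)[keep])
  fs2 <- fitStatistics(d, ss)
  # hand computation: pairs AB=2,AC=4,AD=4,BC=4,BD=4,CD=2 observed;
  # without the internal split the induced cross distances drop to 2
  dd <- c(2, 4, 4, 4, 4, 2); pp <- c(2, 2, 2, 2, 2, 2)
  expect_equal(fs2$fit, 100 * (1 - sum(abs(dd - pp)) / sum(dd)))
  expect_equal(fs2$LSfit, 100 * (1 - sum((dd - pp)^2) / sum(dd^2)))
  # empty split system vs nonzero d -> fit = 0
  empty <- splitSystem(taxonNames(nn), list())
  expect_equal(fitStatistics(d, empty)$fit, 0)
  # all-zero distances are flagged undefined
  z <- matrix(0, 4, 4, dimnames = dimnames(d))
  expect_warning(fz <- fitStatistics(z, nn), "undefined|zero")
  expect_true(is.na(fz$fit))
})

test_that("Z-closure of a single tree returns exactly that tree's splits", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):3,E:1);")
  sn <- zclosureSupernetwork(list(tr), seed = 1)
  ts <- plastophylo:::treeSplits(tr, taxa = taxonNames(sn), trivial = TRUE)
  expect_setequal(vapply(splitSides(sn), plastophylo:::splitKey, ""),
                  vapply(ts$sides, plastophylo:::splitKey, ""))
  # weights are the input branch lengths
  key <- vapply(splitSides(sn), plastophylo:::splitKey, "")
  tkey <- vapply(ts$sides, plastophylo:::splitKey, "")
  expect_equal(splitWeights(sn)[match(tkey, key)], ts$weights)
  # the same tree twice: identical system, weights unchanged
  sn2 <- zclosureSupernetwork(list(tr, tr), seed = 1)
  expect_setequal(vapply(splitSides(sn2), plastophylo:::splitKey, ""), key)
  expect_equal(sort(splitWeights(sn2)), sort(splitWeights(sn)))
})

test_that("conflicting partial trees produce an incompatibility box", {
  # 4 shared taxa in an NNI conflict + 1 private taxon nested inside a
  # clade of each tree: both conflicting quartet splits complete (each
  # private taxon rides along with the clade it nests in), giving four
  # pairwise intersections -> a box
  t1 <- ape::read.tree(text = "(((A,P1),B),(C,D));")
  t2 <- ape::read.tree(text = "(((A,P2),C),(B,D));")
  sn <- zclosureSupernetwork(list(t1, t2), orderings = 10, seed = 3)
  taxa <- taxonNames(sn)
  keys <- vapply(splitSides(sn), function(s)
    paste(sort(taxa[s]), collapse = ","), "")
  hasSplit <- function(side) {
    side <- sort(side)
    if ("A" %in% side) side <- sort(setdiff(taxa, side))
    paste(side, collapse = ",") %in% keys
  }
  expect_true(hasSplit(c("A", "B", "P1", "P2")))   # restriction AB|CD
  expect_true(hasSplit(c("A", "C", "P1", "P2")))   # restriction AC|BD
  n <- length(taxa)
  incompatible <- FALSE
  for (i in seq_along(splitSides(sn))) for (j in seq_along(splitSides(sn)))
    if (i < j && !plastophylo:::splitsCompatible(splitSides(sn)[[i]],
                                                 splitSides(sn)[[j]], n))
      incompatible <- TRUE
  expect_true(incompatible)
})

test_that("supernetworks are reproducible and order-insensitive at high orderings", {
  set.seed(12)
  trees <- lapply(1:3, function(i) {
    tr <- ape::rtree(6)
    tr$tip.label <- sample(paste0("t", 1:8), 6)
    tr
  })
  a <- zclosureSupernetwork(trees, orderings = 20, seed = 5)
  b <- zclosureSupernetwork(trees, orderings = 20, seed = 5)
  expect_identical(splitSides(a), splitSides(b))
  expect_identical(splitWeights(a), splitWeights(b))
  # tree-order insensitivity: on an instance small enough for the pooled
  # closure to converge, reversing the input order changes nothing
  t1 <- ape::read.tree(text = "(((A,P1),B),(C,D));")
  t2 <- ape::read.tree(text = "(((A,P2),C),(B,D));")
  x <- zclosureSupernetwork(list(t1, t2), orderings = 30, seed = 7)
  y <- zclosureSupernetwork(list(t2, t1), orderings = 30, seed = 8)
  expect_setequal(vapply(splitSides(x), plastophylo:::splitKey, ""),
                  vapply(splitSides(y), plastophylo:::splitKey, ""))
})

test_that("disconnected inputs warn and fall back to trivial splits", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((X,Y),(Z,W));")
  expect_warning(sn <- zclosureSupernetwork(list(t1, t2), seed = 2),
                 "connected")
  expect_true(nSplits(sn) >= 8L)   # all trivial splits at least
})
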