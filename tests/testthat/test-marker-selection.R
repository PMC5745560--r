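test_that("locusStats reproduces the hand-computed screening statistics", {
  # 3 species, 10 analysed columns, 2 variable, 8 constant
  aln <- dnaAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                        c = "ATGTACGTAG"))
  st <- locusStats(aln)
  expect_equal(st$analysedSites, 10L)
  expect_equal(st$variableSites, 2L)
  expect_equal(st$constantSites, 8L)
  expect_equal(st$ratio, (2 / 8) / 3)
  # identical rows
  st0 <- locusStats(dnaAlignment(c(a = "ACGT", b = "ACGT")))
  expect_equal(st0$variableSites, 0L)
  expect_equal(st0$ratio, 0)
  expect_equal(st0$pBar, 0)
  # 2 sequences differing at 3 of 12 gap-free columns
  a <- "ACGTACGTACGT"
  b <- "TCGTTCGTTCGT"
  st2 <- locusStats(dnaAlignment(c(a = a, b = b)))
  expect_equal(st2$pBar, 0.25)
})

test_that("deletion rules control which columns are analysed", {
  aln <- dnaAlignment(c(a = "ACGT-C", b = "ACGTAC", c = "ACGTNC"))
  comp <- locusStats(aln, siteDeletion = "complete")
  expect_equal(comp$analysedSites, 5L)   # column 5 dropped
  # column 5 holds -,A,N: a single unambiguous base cannot be compared,
  # so it is dropped under pairwise deletion too
  pw <- locusStats(aln, siteDeletion = "pairwise")
  expect_equal(pw$analysedSites, 5L)
  aln2 <- dnaAlignment(c(a = "ACGT-C", b = "ACGTAC", c = "ACGTAC"))
  expect_equal(locusStats(aln2, siteDeletion = "pairwise")$analysedSites, 6L)
  expect_equal(locusStats(aln2, siteDeletion = "complete")$analysedSites, 5L)
  # degenerate alignment: no analysable column
  deg <- locusStats(dnaAlignment(c(a = "NN", b = "AN")))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$ratio))
  # C = 0: ratio flagged NA, not infinite
  v <- locusStats(dnaAlignment(c(a = "AC", b = "CA")))
  expect_true(is.na(v$ratio))
  expect_false(v$degenerate)
})

test_that("nSpecies override divides the ratio as configured", {
  aln <- dnaAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                        c = "ATGTACGTAG"))
  expect_equal(locusStats(aln, nSpecies = 2)$ratio, (2 / 8) / 2)
})

test_that("p_bar equals an independent double-loop computation", {
  set.seed(31)
  for (i in 1:5) {
    rows <- replicate(6, paste(sample(c("A", "C", "G", "T", "-", "N"), 50,
                                      replace = TRUE,
                                      prob = c(rep(0.23, 4), 0.04, 0.04)),
                               collapse = ""))
    names(rows) <- paste0("t", 1:6)
    expect_equal(locusStats(dnaAlignment(rows))$pBar, bruteMeanP(rows))
  }
})

test_that("statistics are invariant to row and column permutation", {
  set.seed(17)
  rows <- replicate(5, randomDna(40))
  names(rows) <- paste0("t", 1:5)
  aln <- dnaAlignment(rows)
  m <- do.call(rbind, strsplit(rows, ""))
  mp <- m[sample(5), sample(40)]
  alnP <- dnaAlignment(setNames(apply(mp, 1, paste, collapse = ""),
                                paste0("t", 1:5)))
  s1 <- locusStats(aln); s2 <- locusStats(alnP)
  expect_equal(s1$ratio, s2$ratio)
  expect_equal(s1$pBar, s2$pBar)
  expect_equal(sort(pairwiseIdentity(aln)[upper.tri(diag(5))]),
               sort(pairwiseIdentity(alnP)[upper.tri(diag(5))]))
})

test_that("ratio is monotone in the number of variable sites", {
  base <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAAAAAAAAA")
  prev <- -Inf
  for (v in 1:5) {
    rows <- base
    substr(rows["c"], 1, v) <- paste(rep("C", v), collapse = "")
    r <- locusStats(dnaAlignment(rows))$ratio
    expect_gt(r, prev)
    prev <- r
  }
})

test_that("threshold selection follows the strict mean rule", {
  stats <- do.call(rbind, list(
    data.frame(locus = "locus1", n = 5, totalSites = 100, analysedSites = 100,
               variableSites = 1, constantSites = 99, ratio = 0.001,
               pBar = 0.002, degenerate = FALSE),
    data.frame(locus = "locus2", n = 5, totalSites = 100, analysedSites = 100,
               variableSites = 2, constantSites = 98, ratio = 0.003,
               pBar = 0.008, degenerate = FALSE),
    data.frame(locus = "locus3", n = 5, totalSites = 100, analysedSites = 100,
               variableSites = 3, constantSites = 97, ratio = 0.005,
               pBar = 0.011, degenerate = FALSE)))
  rep <- rankAndSelect(stats)
  expect_equal(unname(rep$thresholds), c(0.003, 0.007))
  expect_equal(rep$selected, "locus3")   # locus2 ties the ratio mean: excluded
  expect_equal(rep$stats$locus, c("locus3", "locus2", "locus1"))
  # overrides: shipped plastid IGS defaults
  rep2 <- rankAndSelect(stats, tRatio = igsScreeningDefaults[["tRatio"]],
                        tP = igsScreeningDefaults[["tP"]])
  expect_equal(rep2$selected, c("locus3", "locus2"))
  expect_error(rankAndSelect(stats[0, ]), "two loci|degenerate")
})

test_that("shipped screening defaults carry the documented values", {
  expect_equal(unname(igsScreeningDefaults), c(0.0023, 0.0067))
  expect_equal(unname(intronScreeningDefaults), c(0.0016, 0.0042))
})

test_that("concatenation records spans and counts missing cells", {
  p1 <- setNames(rep(strrep("A", 10), 4), paste0("t", 1:4))
  p2 <- setNames(rep(strrep("C", 20), 4), paste0("t", 1:4))
  sm <- concatenatePartitions(list(x = p1, y = p2))
  expect_equal(Biostrings::width(superAlignment(sm))[1], 30L)
  expect_equal(missingFraction(sm), 0)
  # taxon absent from the 20-col partition -> 20/120 missing
  sm2 <- concatenatePartitions(list(x = p1, y = p2[1:3]))
  expect_equal(missingFraction(sm2), 20 / 120)
  expect_identical(as.character(superAlignment(sm2)[["t4"]]),
                   paste0(strrep("A", 10), strrep("?", 20)))
  # conflicting duplicate rows fail
  bad <- Biostrings::DNAStringSet(c(a = "AAAA", a = "AAAC"))
  expect_error(concatenatePartitions(list(x = bad)), "conflicting")
})

test_that("pre-existing gaps count as missing only when configured", {
  p1 <- c(a = "AC-T", b = "ACGT")
  fillOnly <- concatenatePartitions(list(x = p1))
  expect_equal(missingFraction(fillOnly), 0)
  withGaps <- concatenatePartitions(list(x = p1), countExistingGaps = TRUE)
  expect_equal(missingFraction(withGaps), 1 / 8)
})

test_that("partition slices re-extracted equal the inputs byte for byte", {
  set.seed(23)
  mk <- function(nt, w) setNames(replicate(nt, randomDna(w)),
                                 paste0("t", seq_len(nt)))
  parts <- list(a = mk(4, 12), b = mk(4, 7), c = mk(3, 9))
  sm <- concatenatePartitions(parts)
  for (nm in names(parts)) {
    sl <- extractPartition(sm, nm)
    expect_identical(unname(as.character(sl)[names(parts[[nm]])]),
                     unname(parts[[nm]]))
  }
})

test_that("pairwise identity follows the stated column rules", {
  expect_equal(pairwiseIdentity(dnaAlignment(c(x = "AC-T", y = "ACGT")))[1, 2],
               75)
  id <- pairwiseIdentity(dnaAlignment(c(x = "ACGT", y = "ACGT")))
  expect_equal(id[1, 2], 100)
  # both-gap columns are excluded from the denominator; N matches nothing
  id2 <- pairwiseIdentity(dnaAlignment(c(x = "A--GN", y = "A-CGA")))
  expect_equal(id2[1, 2], 100 * 2 / 4)
  set.seed(3)
  rows <- setNames(replicate(10, randomDna(30)), paste0("t", 1:10))
  m <- pairwiseIdentity(dnaAlignment(rows))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 10))
})
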