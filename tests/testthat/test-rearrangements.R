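test_that("palindrome detection honours definition, threshold and maximality", {
  ec <- findPalindromicRegions("GAATTC", minLen = 6)   # EcoRI site
  expect_equal(nrow(ec), 1L)
  expect_equal(c(ec$start, ec$end), c(1L, 6L))
  expect_equal(nrow(findPalindromicRegions(strrep("A", 50), minLen = 6)), 0L)
  # below threshold
  expect_equal(nrow(findPalindromicRegions("GAATTC", minLen = 8)), 0L)
  # maximal extent reported once: TGAATTCA contains GAATTC but only the
  # 8 bp maximal palindrome is reported
  mx <- findPalindromicRegions("CCTGAATTCAGG", minLen = 4)
  expect_equal(nrow(mx), 1L)
  expect_equal(c(mx$start, mx$end), c(1L, 12L))
})

test_that("a spacer-separated palindrome is found when allowed", {
  # arms GAAT / ATTC around a 3 bp spacer
  s <- paste0(strrep("C", 10), "GAAT", "GGG", "ATTC", strrep("C", 10))
  expect_equal(nrow(findPalindromicRegions(s, minLen = 10)), 0L)
  sp <- findPalindromicRegions(s, minLen = 10, maxSpacer = 3)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$start, sp$end), c(11L, 21L))
})

test_that("palindromes mirror their coordinates under reverse complement", {
  set.seed(41)
  base <- randomDna(300)
  pal <- paste0("ACGTGGATCCACGT")   # not a palindrome; build one properly
  arm <- randomDna(12)
  pal <- paste0(arm, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm))))
  s <- paste0(substr(base, 1, 100), pal, substr(base, 125, 300))
  ev <- findPalindromicRegions(s, minLen = 24)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ev2 <- findPalindromicRegions(rc, minLen = 24)
  n <- nchar(s)
  expect_equal(sort(n - ev$end + 1L), sort(ev2$start))
  expect_equal(sort(n - ev$start + 1L), sort(ev2$end))
})

test_that("dispersed duplications are found and tandem arrays excluded", {
  set.seed(19)
  unit <- randomDna(15)
  bg <- strsplit(randomDna(1000), "")[[1]]
  s <- paste(c(bg[1:100], strsplit(unit, "")[[1]], bg[101:400],
               strsplit(unit, "")[[1]], bg[401:1000]), collapse = "")
  ev <- findDispersedDuplications(s)
  ev <- ev[ev$length >= 15 & ev$copies >= 2, ]
  expect_true(nrow(ev) >= 2L)
  expect_true(any(ev$start == 101L))
  expect_true(any(ev$start == 416L))
  # tandem only: two adjacent copies are one site, excluded
  tand <- paste0(substr(s, 1, 100), unit, unit, substr(s, 500, 1000))
  evt <- findDispersedDuplications(tand)
  expect_false(any(vapply(seq_len(nrow(evt)), function(i)
    evt$start[i] <= 115 & evt$end[i] >= 101, FALSE)))
})

test_that("duplication scan agrees with a brute-force k-mer table", {
  set.seed(29)
  for (i in 1:3) {
    s <- randomDna(3000)
    ev <- findDispersedDuplications(s, minLen = 10)
    # oracle: all 10-mers occurring >= 2 times at non-adjacent sites
    k <- 10
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    tab <- table(km)
    rep10 <- names(tab[tab >= 2])
    # every reported event must contain a repeated 10-mer, and every
    # repeated non-tandem 10-mer must fall inside some reported event
    for (r in rep10) {
      pos <- which(km == r)
      if (all(diff(pos) <= k)) next   # tandem/overlapping run
      hit <- any(vapply(seq_len(nrow(ev)), function(e)
        any(pos >= ev$start[e] & pos + k - 1 <= ev$end[e]), FALSE))
      expect_true(hit, info = sprintf("iter %d kmer %s", i, r))
    }
    if (nrow(ev)) expect_true(all(ev$length >= 10))
  }
})

test_that("inversions are recovered exactly and controls stay clean", {
  set.seed(2)
  ref <- randomDna(2000)
  seg <- substr(ref, 501, 544)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  q <- paste0(substr(ref, 1, 500), rc, substr(ref, 545, 2000))
  ev <- findInversions(q, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(501L, 544L))
  expect_equal(c(ev$refStart, ev$refEnd), c(501L, 544L))
  # identical sequences: none
  expect_equal(nrow(findInversions(ref, ref)), 0L)
  # below threshold: none
  seg2 <- substr(ref, 501, 515)
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg2)))
  q2 <- paste0(substr(ref, 1, 500), rc2, substr(ref, 516, 2000))
  expect_equal(nrow(findInversions(q2, ref, minLen = 20)), 0L)
  # no homology at all -> empty with warning
  set.seed(3)
  expect_warning(out <- findInversions(randomDna(300), randomDna(300)),
                 "homology")
  expect_equal(nrow(out), 0L)
})

test_that("gap runs become polarized indel events", {
  g101 <- strrep("-", 101)
  keep <- randomDna(150, 7)
  rows <- c(a = paste0(substr(keep, 1, 20), g101, substr(keep, 122, 150)),
            b = keep, c = keep, d = keep)
  ev <- gapEvents(dnaAlignment(rows))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length, 101L)
  expect_equal(ev$sharing, "unique")
  expect_equal(ev$carriers, "a")
  # identical 15-column gap in 4 of 8 rows -> one shared deletion
  base <- randomDna(60, 8)
  gapped <- paste0(substr(base, 1, 10), strrep("-", 15), substr(base, 26, 60))
  rows8 <- setNames(c(rep(gapped, 4), rep(base, 4)), letters[1:8])
  ev8 <- gapEvents(dnaAlignment(rows8))
  expect_equal(nrow(ev8), 1L)
  expect_equal(ev8$kind, "deletion")
  expect_equal(ev8$copies, 4L)
  expect_equal(ev8$sharing, "shared")
  # majority-gap column runs are insertions carried by the gapped rows
  rows5 <- setNames(c(rep(gapped, 4), base), letters[1:5])
  expect_equal(gapEvents(dnaAlignment(rows5))$kind, "insertion")
  # gap-free alignment
  expect_equal(nrow(gapEvents(dnaAlignment(setNames(rep(base, 3),
                                                    c("x", "y", "z"))))), 0L)
  expect_error(gapEvents(dnaAlignment(c(a = "A-", b = "AA"))), "3 rows")
})

test_that("gap events are invariant to row order", {
  set.seed(9)
  base <- randomDna(50)
  rows <- setNames(c(paste0("----", substr(base, 5, 50)),
                     base,
                     paste0(substr(base, 1, 30), "-----",
                            substr(base, 36, 50)),
                     base), c("a", "b", "c", "d"))
  e1 <- gapEvents(dnaAlignment(rows))
  e2 <- gapEvents(dnaAlignment(rows[c(3, 1, 4, 2)]))
  expect_identical(e1, e2)
})

test_that("event-free random controls yield no events at default thresholds", {
  set.seed(1234)
  s <- randomDna(10000)
  expect_equal(nrow(findPalindromicRegions(s)), 0L)
  expect_equal(nrow(findDispersedDuplications(s)), 0L)
  s2 <- randomDna(10000)
  expect_equal(nrow(suppressWarnings(findInversions(s, s2))), 0L)
})
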