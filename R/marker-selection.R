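#' @include AllClasses.R utils.R
NULL

#' Per-locus variability statistics
#'
#' Computes the two screening statistics used to rank candidate plastid
#' markers:
#'
#' * the **normalized divergence ratio** `r = (V / C) / n`, where `V` and
#'   `C` are the numbers of variable and constant sites among the analysed
#'   alignment columns and `n` the number of species considered, and
#' * the **average uncorrected p-distance** `p_bar`, the mean over all
#'   unordered sequence pairs of (mismatches / pairwise-compared sites).
#'
#' Site classification and the pairwise distances use separate deletion
#' rules (both configurable): under `"complete"` deletion any column
#' containing a gap, `N` or other ambiguity in any row is excluded; under
#' `"pairwise"` deletion a column is analysed when at least two rows carry
#' an unambiguous base there. Non-ACGT letters are always treated as
#' missing, never as states.
#'
#' @param aln a [DNAAlignment-class] (or coercible; at least 2 rows).
#' @param siteDeletion deletion rule for the V/C site classification
#'   (default `"complete"`).
#' @param pairDeletion deletion rule for `p_bar` (default `"pairwise"`).
#' @param nSpecies number of species considered; defaults to the number of
#'   rows, override when several accessions per species are present.
#' @param locus locus label carried into the output.
#' @return a one-row data.frame: `locus`, `n`, `totalSites`,
#'   `analysedSites`, `variableSites`, `constantSites`, `ratio`, `pBar`,
#'   `degenerate`. `ratio` is `NA` (flagged via `degenerate` or a zero
#'   constant count), never infinite.
#' @examples
#' aln <- dnaAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ATGTACGTAG"))
#' locusStats(aln)$ratio   # (2/8)/3
#' @export
locusStats <- function(aln, siteDeletion = c("complete", "pairwise"),
                       pairDeletion = c("pairwise", "complete"),
                       nSpecies = NULL, locus = NA_character_) {
  siteDeletion <- match.arg(siteDeletion)
  pairDeletion <- match.arg(pairDeletion)
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("at least two sequences are required")
  n <- if (is.null(nSpecies)) nrow(m) else as.integer(nSpecies)
  ok <- isACGT(m)
  analysedCols <- if (siteDeletion == "complete")
    which(colSums(ok) == nrow(m)) else which(colSums(ok) >= 2L)
  V <- C <- 0L
  for (j in analysedCols) {
    states <- unique(m[ok[, j], j])
    if (length(states) > 1L) V <- V + 1L else C <- C + 1L
  }
  degenerate <- length(analysedCols) == 0L
  ratio <- if (degenerate || C == 0L) NA_real_ else (V / C) / n
  pBar <- if (degenerate) NA_real_ else
    mean(pairwisePDistances(m, pairDeletion)[upper.tri(diag(nrow(m)))])
  data.frame(locus = locus, n = n, totalSites = ncol(m),
             analysedSites = length(analysedCols), variableSites = V,
             constantSites = C, ratio = ratio, pBar = pBar,
             degenerate = degenerate)
}

# matrix of uncorrected p-distances between rows of a character matrix
pairwisePDistances <- function(m, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  ok <- isACGT(m)
  if (deletion == "complete") {
    keep <- colSums(ok) == nrow(m)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  nr <- nrow(m)
  d <- matrix(0, nr, nr, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop(sprintf("no comparable sites between '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
  }
  d
}

#' Rank loci and select markers above average-variability thresholds
#'
#' A locus qualifies as a candidate marker when its normalized divergence
#' ratio and its average p-distance are both *strictly* above the
#' thresholds. By default each threshold is the arithmetic mean of the
#' statistic over loci with defined values; pass `tRatio`/`tP` to override
#' (e.g. with the shipped plastid IGS screening defaults,
#' [igsScreeningDefaults]).
#'
#' @param stats data.frame of per-locus rows as returned by [locusStats()]
#'   (rbind them), at least two with defined statistics.
#' @param tRatio,tP optional threshold overrides.
#' @return a list of class `"selectionReport"`: `stats` (ranked by ratio
#'   descending, ties by `pBar` then locus name, with a `selected` column),
#'   `thresholds`, and `selected` (the qualifying locus names, in ranked
#'   order).
#' @export
rankAndSelect <- function(stats, tRatio = NULL, tP = NULL) {
  def <- !is.na(stats$ratio) & !is.na(stats$pBar)
  if (sum(def) < 2L && (is.null(tRatio) || is.null(tP)))
    stop("need at least two loci with defined statistics to set thresholds")
  if (!any(def)) stop("all loci are degenerate")
  if (is.null(tRatio)) tRatio <- mean(stats$ratio[def])
  if (is.null(tP)) tP <- mean(stats$pBar[def])
  sel <- def & stats$ratio > tRatio & stats$pBar > tP
  stats$selected <- sel
  o <- order(-replace(stats$ratio, is.na(stats$ratio), -Inf),
             -replace(stats$pBar, is.na(stats$pBar), -Inf), stats$locus)
  stats <- stats[o, , drop = FALSE]
  rownames(stats) <- NULL
  structure(list(stats = stats,
                 thresholds = c(tRatio = tRatio, tP = tP),
                 selected = stats$locus[stats$selected]),
            class = "selectionReport")
}

#' @export
print.selectionReport <- function(x, ...) {
  cat(sprintf("Marker selection: %d/%d loci above (tRatio=%.4g, tP=%.4g)\n",
              length(x$selected), nrow(x$stats),
              x$thresholds["tRatio"], x$thresholds["tP"]))
  print(x$stats[, c("locus", "n", "ratio", "pBar", "selected")], ...)
  invisible(x)
}

#' Shipped threshold defaults for plastid IGS screening
#'
#' Reference thresholds for screening intergenic spacers of congeneric
#' plastomes: average normalized divergence ratio 0.0023 and average
#' p-distance 0.0067 (the corresponding intron screen used 0.0016 and
#' 0.0042).
#' @format named numeric vector with elements `tRatio` and `tP`.
#' @export
igsScreeningDefaults <- c(tRatio = 0.0023, tP = 0.0067)

#' @rdname igsScreeningDefaults
#' @export
intronScreeningDefaults <- c(tRatio = 0.0016, tP = 0.0042)

#' Concatenate aligned partitions into a supermatrix
#'
#' Taxa are unioned across partitions; blocks for taxa absent from a
#' partition are filled with `fill` (default `"?"`). The fraction of
#' missing data counts the filled cells and, when
#' `countExistingGaps = TRUE`, also pre-existing gap (`-`) cells of the
#' input alignments.
#'
#' @param partitions named list of alignments ([DNAAlignment-class],
#'   `DNAStringSet`, or named character vectors).
#' @param fill single fill character for absent blocks.
#' @param countExistingGaps include input `-` cells in `missingFraction`?
#' @return a [Supermatrix-class].
#' @export
concatenatePartitions <- function(partitions, fill = "?",
                                  countExistingGaps = FALSE) {
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    names(partitions) <- paste0("part", seq_along(partitions))
  mats <- lapply(partitions, function(p) {
    m <- alignmentMatrix(p)
    if (anyDuplicated(rownames(m))) {
      rows <- split(seq_len(nrow(m)), rownames(m))
      for (r in rows[lengths(rows) > 1L]) {
        s <- apply(m[r, , drop = FALSE], 1L, paste, collapse = "")
        if (length(unique(s)) > 1L)
          stop("duplicated taxon with conflicting sequences in one partition")
      }
      m <- m[!duplicated(rownames(m)), , drop = FALSE]
    }
    m
  })
  taxa <- unique(unlist(lapply(mats, rownames)))
  if (length(taxa) < 1L) stop("no taxa")
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (!length(shared)) stop("partitions share no taxa")
  widths <- vapply(mats, ncol, 0L)
  total <- sum(widths)
  rows <- matrix(fill, length(taxa), total, dimnames = list(taxa, NULL))
  start <- cumsum(c(1L, widths[-length(widths)]))
  filled <- 0L; gapCells <- 0L
  for (k in seq_along(mats)) {
    cols <- start[k]:(start[k] + widths[k] - 1L)
    present <- intersect(taxa, rownames(mats[[k]]))
    rows[present, cols] <- mats[[k]][present, , drop = FALSE]
    filled <- filled + (length(taxa) - length(present)) * widths[k]
    gapCells <- gapCells + sum(mats[[k]][present, , drop = FALSE] == "-")
  }
  missing <- filled + if (countExistingGaps) gapCells else 0L
  aln <- BStringSet(apply(rows, 1L, paste, collapse = ""))
  names(aln) <- taxa
  new("Supermatrix", alignment = aln,
      partitions = data.frame(locus = names(partitions),
                              start = as.integer(start),
                              end = as.integer(start + widths - 1L)),
      missingFraction = unname(missing / (length(taxa) * total)),
      fill = fill)
}

#' Extract one partition from a supermatrix
#'
#' @param sm a [Supermatrix-class].
#' @param locus partition name.
#' @param dropAbsent drop rows that are entirely fill characters?
#' @return a `BStringSet` of the partition's columns.
#' @export
extractPartition <- function(sm, locus, dropAbsent = TRUE) {
  i <- match(locus, sm@partitions$locus)
  if (is.na(i)) stop(sprintf("no partition '%s'", locus))
  x <- subseq(sm@alignment, sm@partitions$start[i], sm@partitions$end[i])
  if (dropAbsent) {
    keep <- vapply(as.character(x), function(s)
      !all(seqChars(s) == sm@fill), FALSE)
    x <- x[keep]
  }
  x
}

#' Pairwise percent identity of aligned sequences
#'
#' `identity(i, j)` is the percentage of identical residue columns among
#' the columns where the two rows are not both gaps. A gap aligned to a
#' residue counts as a mismatch; `N` (and any other ambiguity or `?`)
#' matches nothing. The matrix is symmetric with a diagonal of 100.
#'
#' @param aln a [DNAAlignment-class] or coercible (at least 2 rows).
#' @return symmetric numeric matrix of identity percentages.
#' @examples
#' pairwiseIdentity(dnaAlignment(c(x = "AC-T", y = "ACGT")))[1, 2]  # 75
#' @export
pairwiseIdentity <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("at least two sequences are required")
  ok <- isACGT(m)
  gap <- m == "-"
  nr <- nrow(m)
  id <- matrix(100, nr, nr, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
    comp <- !(gap[i, ] & gap[j, ])
    match <- ok[i, ] & ok[j, ] & m[i, ] == m[j, ]
    id[i, j] <- id[j, i] <- 100 * sum(match & comp) / sum(comp)
  }
  id
}
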