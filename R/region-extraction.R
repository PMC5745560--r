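#' @include AllClasses.R utils.R
NULL

#' Extract non-coding loci from an annotated genome
#'
#' Derives introns and intergenic spacers (IGS), the two classes of
#' non-coding plastid loci used for marker screening.
#'
#' * **Introns** are the gaps between consecutive exons of one multi-exon
#'   feature, named `"<gene>_intron<k>"` with `k` counted in transcription
#'   order; the returned sequence is reverse-complemented for genes on the
#'   minus strand. Trans-spliced features are skipped.
#' * **IGS** are the maximal gaps between consecutive gene-level spans (the
#'   union of a feature's exons) along the unfolded circle, named
#'   `"<geneA>-<geneB>"` by the flanking genes in genomic order; strand is
#'   ignored for naming. Features fully nested inside another feature's span
#'   are ignored for boundary computation, as are duplicate spans of the
#'   same gene (first occurrence by coordinate wins). For circular genomes
#'   the wrap-around spacer is included once. Overlapping genes produce no
#'   spacer; they are recorded in the `skipped` attribute and flagged with a
#'   single collected warning, never an error.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param kind `"igs"` or `"intron"`.
#' @param minLen minimum locus length to report (default 1; zero-length
#'   gaps are always omitted).
#' @return a data.frame with columns `locus`, `genome`, `start`, `end`
#'   (1-based inclusive on the forward strand; for a wrap-around IGS
#'   `end = start + len - 1` may exceed the genome length), `strand`,
#'   `length`, `sequence`. Attribute `skipped` lists gene pairs whose
#'   overlap precluded a spacer.
#' @examples
#' g <- annotatedGenome("t", paste(rep("ACGT", 100), collapse = ""),
#'   features = S4Vectors::DataFrame(
#'     name = c("gA", "gB"), kind = "gene", strand = 1L,
#'     exons = IRanges::IRangesList(IRanges::IRanges(1, 100),
#'                                  IRanges::IRanges(151, 300))))
#' extractNoncoding(g, "igs")   # one IGS "gA-gB" of length 50
#' @export
extractNoncoding <- function(genome, kind = c("igs", "intron"), minLen = 1L) {
  kind <- match.arg(kind)
  fts <- genome@features
  seq <- as.character(genome@sequence)
  L <- nchar(seq)
  rows <- list()
  skipped <- character()

  if (kind == "intron") {
    ok <- !fts$transSpliced & vapply(fts$exons, length, 0L) >= 2L
    for (i in which(ok)) {
      ex <- fts$exons[[i]]
      st <- IRanges::start(ex); en <- IRanges::end(ex)
      nIntron <- length(st) - 1L
      for (j in seq_len(nIntron)) {
        a <- en[j] + 1L; b <- st[j + 1L] - 1L
        if (b < a) next
        # transcription-order numbering: minus-strand genes count from the
        # rightmost intron
        k <- if (fts$strand[i] < 0L) nIntron - j + 1L else j
        s <- substr(seq, a, b)
        if (fts$strand[i] < 0L) s <- revcompChar(s)
        if (nchar(s) < minLen) next
        rows[[length(rows) + 1L]] <- data.frame(
          locus = sprintf("%s_intron%d", fts$name[i], k),
          genome = genome@id, start = a, end = b,
          strand = fts$strand[i], length = b - a + 1L, sequence = s)
      }
    }
  } else {
    spans <- geneSpans(fts)
    if (nrow(spans) >= 2L) {
      o <- order(spans$start, spans$end)
      spans <- spans[o, ]
      m <- nrow(spans)
      pairs <- cbind(seq_len(m), c(seq_len(m)[-1L], 1L))
      last <- if (genome@circular) m else m - 1L
      for (p in seq_len(last)) {
        i <- pairs[p, 1L]; j <- pairs[p, 2L]
        a <- spans$end[i] + 1L
        b <- if (j == 1L) spans$start[j] - 1L + L else spans$start[j] - 1L
        if (b < a) {
          if (b - a + 1L < 0L)
            skipped <- c(skipped,
                         sprintf("%s-%s", spans$name[i], spans$name[j]))
          next
        }
        s <- if (b <= L) substr(seq, a, b) else
          paste0(substr(seq, a, L), substr(seq, 1L, b - L))
        if (nchar(s) < minLen) next
        rows[[length(rows) + 1L]] <- data.frame(
          locus = sprintf("%s-%s", spans$name[i], spans$name[j]),
          genome = genome@id, start = a, end = b, strand = 1L,
          length = b - a + 1L, sequence = s)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), genome = character(), start = integer(),
               end = integer(), strand = integer(), length = integer(),
               sequence = character())
  out <- out[order(out$start, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- unique(skipped)
  if (length(skipped))
    warning(sprintf("%s: overlapping genes, no spacer for: %s", genome@id,
                    paste(unique(skipped), collapse = ", ")), call. = FALSE)
  out
}

# gene-level spans used for IGS boundaries: per feature the union of its
# exons; 'gene' features take precedence over same-named CDS/tRNA/rRNA
# duplicates; spans nested inside another span are dropped
geneSpans <- function(fts) {
  if (!nrow(fts))
    return(data.frame(name = character(), start = integer(), end = integer()))
  start <- vapply(fts$exons, function(e) min(IRanges::start(e)), 0L)
  end <- vapply(fts$exons, function(e) max(IRanges::end(e)), 0L)
  df <- data.frame(name = fts$name, kind = fts$kind, start = start, end = end)
  # 'gene' rows win over same-named CDS/tRNA/rRNA duplicates of the same
  # span (GenBank records usually carry both); genuinely repeated gene
  # spans (inverted-repeat copies) are kept
  isGene <- df$kind == "gene"
  drop <- !isGene & paste(df$name, df$start, df$end) %in%
    paste(df$name, df$start, df$end)[isGene]
  df <- df[!drop, , drop = FALSE]
  df <- df[order(df$start, df$end, df$name), , drop = FALSE]
  df <- df[!duplicated(df[, c("name", "start", "end")]), , drop = FALSE]
  # drop spans fully nested in another span
  nested <- vapply(seq_len(nrow(df)), function(i)
    any(df$start <= df$start[i] & df$end >= df$end[i] &
          seq_len(nrow(df)) != i), FALSE)
  df <- df[!nested, , drop = FALSE]
  df[, c("name", "start", "end")]
}

#' Collect homologous copies of one locus across genomes
#'
#' Runs [extractNoncoding()] on each genome and gathers the sequences of
#' `locusId`. Genomes lacking the locus are reported as absent (never
#' padded); genomes carrying several copies (e.g. loci duplicated in an
#' inverted repeat) contribute their first copy by coordinate and are
#' listed in the `duplicated` slot.
#'
#' @param genomes list of [AnnotatedGenome-class] objects.
#' @param locusId canonical locus name; the kind is inferred from the name
#'   (`"A-B"` = IGS, `"g_intron<k>"` = intron).
#' @return a [LocusSet-class].
#' @export
harvestLocus <- function(genomes, locusId) {
  kind <- if (grepl("_intron[0-9]+$", locusId)) "intron" else "igs"
  seqs <- character(); absent <- character(); dupl <- character()
  for (g in genomes) {
    regs <- suppressWarnings(extractNoncoding(g, kind))
    hit <- regs[regs$locus == locusId, , drop = FALSE]
    if (!nrow(hit)) { absent <- c(absent, g@id); next }
    if (nrow(hit) > 1L) {
      dupl <- c(dupl, g@id)
      hit <- hit[which.min(hit$start), , drop = FALSE]
    }
    seqs[g@id] <- hit$sequence
  }
  if (length(seqs) < 2L)
    stop(sprintf("insufficient sampling: locus '%s' found in %d genome(s)",
                 locusId, length(seqs)))
  new("LocusSet", locusId = locusId, members = DNAStringSet(seqs),
      absent = absent, duplicated = dupl)
}

#' Inventory of all non-coding loci across genomes
#'
#' @param genomes list of [AnnotatedGenome-class] objects.
#' @param kind `"igs"`, `"intron"`, or `"both"`.
#' @param minLen minimum locus length.
#' @return a data.frame: one row per (locus, genome) occurrence.
#' @export
locusInventory <- function(genomes, kind = c("both", "igs", "intron"),
                           minLen = 1L) {
  kind <- match.arg(kind)
  kinds <- if (kind == "both") c("igs", "intron") else kind
  out <- list()
  for (g in genomes) for (k in kinds)
    out[[length(out) + 1L]] <- suppressWarnings(
      extractNoncoding(g, k, minLen = minLen))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
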