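#' @include AllClasses.R utils.R
NULL

# empty event table with the standard columns
emptyEvents <- function() {
  data.frame(kind = character(), locus = character(), carriers = character(),
             start = integer(), end = integer(), length = integer(),
             refStart = integer(), refEnd = integer(), copies = integer(),
             sharing = character())
}

eventRow <- function(kind, start, end, locus = NA_character_,
                     carriers = NA_character_, refStart = NA_integer_,
                     refEnd = NA_integer_, copies = NA_integer_,
                     sharing = NA_character_) {
  data.frame(kind = kind, locus = locus, carriers = carriers,
             start = as.integer(start), end = as.integer(end),
             length = as.integer(end - start + 1L),
             refStart = as.integer(refStart), refEnd = as.integer(refEnd),
             copies = as.integer(copies), sharing = sharing)
}

comp1 <- c(A = "T", C = "G", G = "C", T = "A")

#' Find palindromic regions in a DNA sequence
#'
#' A DNA palindrome is an even-length substring equal to its own reverse
#' complement (e.g. the EcoRI site `GAATTC`); optionally the two arms may
#' be separated by a spacer of up to `maxSpacer` bases. Each maximal extent
#' is reported once; regions contained in a longer reported region are
#' suppressed. `N` and other ambiguity codes match nothing.
#'
#' @param seq ungapped DNA (character scalar, `DNAString`, or an
#'   [AnnotatedGenome-class]).
#' @param minLen minimum total event length (arms plus spacer), default 20.
#' @param maxSpacer maximum spacer between the two arms, default 0.
#' @return event data.frame (`kind = "palindrome"`, 1-based inclusive
#'   `start`/`end` on the sequence).
#' @examples
#' findPalindromicRegions("GAATTC", minLen = 6)   # the EcoRI site
#' @export
findPalindromicRegions <- function(seq, minLen = 20L, maxSpacer = 0L) {
  v <- seqChars(extractSeq(seq))
  n <- length(v)
  cv <- unname(comp1[v])          # NA for non-ACGT: matches nothing
  hits <- list()
  for (g in 0:maxSpacer) {
    for (cc in seq_len(max(0L, n - 1L - g))) {
      # arms v[cc-k+1 .. cc] and v[cc+g+1 .. cc+g+k]
      k <- 0L
      while (cc - k >= 1L && cc + g + 1L + k <= n &&
             !is.na(cv[cc + g + 1L + k]) &&
             v[cc - k] == cv[cc + g + 1L + k]) k <- k + 1L
      if (k >= 1L && 2L * k + g >= minLen)
        hits[[length(hits) + 1L]] <- c(cc - k + 1L, cc + g + k)
    }
  }
  if (!length(hits)) return(emptyEvents())
  iv <- unique(do.call(rbind, hits))
  keep <- vapply(seq_len(nrow(iv)), function(i)
    !any(iv[, 1L] <= iv[i, 1L] & iv[, 2L] >= iv[i, 2L] &
           (iv[, 1L] != iv[i, 1L] | iv[, 2L] != iv[i, 2L])), FALSE)
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(iv)), function(i)
    eventRow("palindrome", iv[i, 1L], iv[i, 2L])))
}

extractSeq <- function(x) {
  if (is(x, "AnnotatedGenome")) return(as.character(x@sequence))
  toupper(as.character(x))
}

#' Find dispersed (non-tandem) duplications
#'
#' Detects maximal repeated substrings of length at least `minLen` that
#' occur at `minCopies` or more *non-tandem* sites: occurrences that abut
#' or overlap are merged into one site, so a purely tandem array counts as
#' a single site and is not reported.
#'
#' Seeds are exact `minLen`-mers occurring more than once; each occurrence
#' class is extended to its maximal shared unit and classes converging on
#' the same unit are reported once.
#'
#' @param seq ungapped DNA.
#' @param minLen minimum repeat-unit length, default 15.
#' @param minCopies minimum number of non-tandem sites, default 2.
#' @return event data.frame: one row per occurrence, grouped rows share a
#'   `locus` identifier of the form `dup<N>`; `copies` gives the number of
#'   non-tandem sites.
#' @export
findDispersedDuplications <- function(seq, minLen = 15L, minCopies = 2L) {
  s <- extractSeq(seq)
  n <- nchar(s)
  k <- as.integer(minLen)
  if (n < 2L * k) return(emptyEvents())
  v <- seqChars(s)
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  pos <- split(seq_along(kmers), kmers)
  pos <- pos[lengths(pos) >= 2L & !grepl("[^ACGT]", names(pos))]
  units <- list()
  for (P in pos) {
    # maximal shared extension of the occurrence class
    left <- 0L
    while (all(P - left - 1L >= 1L) &&
           length(u <- unique(v[P - left - 1L])) == 1L && u %in% comp1)
      left <- left + 1L
    right <- 0L
    while (all(P + k + right <= n) &&
           length(u <- unique(v[P + k + right])) == 1L && u %in% comp1)
      right <- right + 1L
    st <- P - left
    L <- k + left + right
    key <- paste(c(L, sort(st)), collapse = ",")
    if (is.null(units[[key]])) units[[key]] <- list(start = sort(st), len = L)
  }
  if (!length(units)) return(emptyEvents())
  # drop units whose occurrence set is a shifted sub-run of a longer unit
  desc <- order(-vapply(units, `[[`, 0L, "len"))
  covered <- function(u, w) # all occurrences of u fall inside occurrences of w
    all(vapply(u$start, function(p)
      any(w$start <= p & p + u$len - 1L <= w$start + w$len - 1L), FALSE))
  keep <- rep(TRUE, length(units))
  for (a in seq_along(desc)) for (b in seq_len(a - 1L)) {
    if (keep[desc[b]] && keep[desc[a]] &&
        covered(units[[desc[a]]], units[[desc[b]]])) keep[desc[a]] <- FALSE
  }
  units <- units[keep]
  out <- list(); id <- 0L
  for (u in units) {
    st <- sort(u$start); L <- u$len
    # merge tandem/overlapping occurrences into sites
    site <- cumsum(c(1L, as.integer(st[-1L] > st[-length(st)] + L)))
    if (max(site) < minCopies) next
    id <- id + 1L
    for (p in st)
      out[[length(out) + 1L]] <-
        eventRow("duplication", p, p + L - 1L,
                 locus = sprintf("dup%d", id), copies = max(site))
  }
  if (!length(out)) return(emptyEvents())
  do.call(rbind, out)
}

#' Find local inversions between two homologous sequences
#'
#' Reports segments where the query matches the reverse complement of the
#' reference but not the forward strand. Detection is by exact `k`-mer
#' seeding against the reverse strand followed by single-linkage chaining
#' of seeds on a common anti-diagonal; a chained segment is reported when
#' it is at least `minLen` long, the query segment equals the reverse
#' complement of the implied reference segment, and the two segments are
#' not forward-identical (which excludes palindromes).
#'
#' @param query,reference ungapped homologous DNA sequences.
#' @param minLen minimum inversion length, default 20.
#' @param k seed k-mer size, default 12.
#' @param chainGap maximum seed gap bridged during chaining, default 5.
#' @return event data.frame (`kind = "inversion"`) with query coordinates
#'   in `start`/`end` and reference coordinates in `refStart`/`refEnd`;
#'   empty (with a warning when no seeds at all were found) otherwise.
#' @export
findInversions <- function(query, reference, minLen = 20L, k = 12L,
                           chainGap = 5L) {
  q <- extractSeq(query); r <- extractSeq(reference)
  nq <- nchar(q); nr <- nchar(r)
  if (nq < k || nr < k) return(emptyEvents())
  rk <- substring(r, 1:(nr - k + 1L), k:nr)
  idx <- split(seq_along(rk), rk)
  qk <- substring(q, 1:(nq - k + 1L), k:nq)
  # reverse complement of every query k-mer via one whole-sequence revcomp
  rcq <- revcompChar(q)
  ii <- 1:(nq - k + 1L)
  rck <- substring(rcq, nq - ii - k + 2L, nq - ii + 1L)
  ok <- !grepl("[^ACGT]", qk)
  anyForward <- any(qk[ok] %in% names(idx))
  hitAt <- match(rck, names(idx))
  hitAt[!ok] <- NA_integer_
  seeds <- list()
  for (i in which(!is.na(hitAt)))
    for (j in idx[[hitAt[i]]])
      seeds[[length(seeds) + 1L]] <- c(i = i, j = j)
  if (!length(seeds)) {
    if (!anyForward)
      warning("no homology detectable between query and reference")
    return(emptyEvents())
  }
  sd <- do.call(rbind, seeds)
  out <- list()
  for (adiag in unique(sd[, "i"] + sd[, "j"])) {
    grp <- sd[sd[, "i"] + sd[, "j"] == adiag, , drop = FALSE]
    is <- sort(grp[, "i"])
    brk <- cumsum(c(1L, as.integer(diff(is) > k + chainGap)))
    for (b in unique(brk)) {
      ii <- is[brk == b]
      qs <- min(ii); qe <- max(ii) + k - 1L
      if (qe - qs + 1L < minLen) next
      # query p maps to ref (i + j + k - 1) - p on this anti-diagonal
      rseg <- c(adiag + k - 1L - qe, adiag + k - 1L - qs)
      qstr <- substr(q, qs, qe)
      if (!identical(qstr, revcompChar(substr(r, rseg[1L], rseg[2L])))) next
      if (identical(qstr, substr(r, rseg[1L], rseg[2L]))) next  # palindrome
      out[[length(out) + 1L]] <-
        eventRow("inversion", qs, qe, refStart = rseg[1L], refEnd = rseg[2L])
    }
  }
  if (!length(out)) return(emptyEvents())
  ev <- do.call(rbind, out)
  ev[!duplicated(ev[, c("start", "end")]), , drop = FALSE]
}

#' Indel events from gap runs of an alignment
#'
#' Maximal gap runs per row are merged into events keyed by their exact
#' (start, length); rows sharing the identical run are its carriers
#' (alignment placement, not mere sequence identity, defines homology
#' here). An event is a deletion when its carriers are in the minority,
#' an insertion when rows *with* the gap form the majority (i.e. the
#' residues are the derived state); `sharing` is `"unique"` for a single
#' carrier and `"shared"` otherwise.
#'
#' @param aln a [DNAAlignment-class] with at least 3 rows (needed to
#'   polarize shared against unique events).
#' @return event data.frame with alignment-column coordinates.
#' @export
gapEvents <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 3L) stop("at least 3 rows are required to polarize events")
  runs <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (w in which(r$values)) {
      key <- sprintf("%d:%d", starts[w], r$lengths[w])
      runs[[key]] <- c(runs[[key]], rownames(m)[i])
    }
  }
  if (!length(runs)) return(emptyEvents())
  out <- lapply(names(runs), function(key) {
    sl <- as.integer(strsplit(key, ":", fixed = TRUE)[[1L]])
    carriers <- runs[[key]]
    kind <- if (length(carriers) <= nrow(m) / 2) "deletion" else "insertion"
    eventRow(kind, sl[1L], sl[1L] + sl[2L] - 1L,
             carriers = paste(sort(carriers), collapse = ","),
             copies = length(carriers),
             sharing = if (length(carriers) == 1L) "unique" else "shared")
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$start, ev$length), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Scan a set of sequences for all rearrangement classes
#'
#' Convenience wrapper running the palindrome, duplication, inversion and
#' indel detectors with their default thresholds.
#'
#' @param genomes list of [AnnotatedGenome-class] or named sequences.
#' @param reference optional reference id for inversion detection
#'   (defaults to the first genome).
#' @param aln optional alignment for [gapEvents()].
#' @param minPalindrome,minDuplication,minInversion length thresholds.
#' @return combined event data.frame with a `genome` column.
#' @export
scanRearrangements <- function(genomes, reference = NULL, aln = NULL,
                               minPalindrome = 20L, minDuplication = 15L,
                               minInversion = 20L) {
  ids <- vapply(genomes, function(g)
    if (is(g, "AnnotatedGenome")) g@id else NA_character_, "")
  if (anyNA(ids)) ids <- names(genomes)
  refId <- if (is.null(reference)) ids[1L] else reference
  ref <- genomes[[match(refId, ids)]]
  out <- list()
  for (i in seq_along(genomes)) {
    ev <- rbind(
      findPalindromicRegions(genomes[[i]], minLen = minPalindrome),
      findDispersedDuplications(genomes[[i]], minLen = minDuplication))
    if (ids[i] != refId)
      ev <- rbind(ev, findInversions(genomes[[i]], ref,
                                     minLen = minInversion))
    if (nrow(ev)) ev$genome <- ids[i]
    out[[i]] <- ev
  }
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0L])
  if (is.null(res)) {
    res <- emptyEvents(); res$genome <- character()
  }
  if (!is.null(aln)) {
    ge <- gapEvents(aln)
    if (nrow(ge)) { ge$genome <- NA_character_; res <- rbind(res, ge) }
  }
  rownames(res) <- NULL
  res
}

#' Write events as BED-like text (0-based half-open intervals)
#'
#' @param events event data.frame from the scanners.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeEventsBed <- function(events, file) {
  bed <- data.frame(chrom = ifelse(is.na(events$genome), ".", events$genome),
                    start = events$start - 1L, end = events$end,
                    name = paste0(events$kind,
                                  ifelse(is.na(events$locus), "",
                                         paste0(":", events$locus))))
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
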