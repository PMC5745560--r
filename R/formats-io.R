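#' @include AllClasses.R utils.R
#' @importFrom Biostrings readDNAStringSet writeXStringSet
NULL

## ---- GenBank flat files ---------------------------------------------------

#' Read an annotated genome from a GenBank flat file
#'
#' Parses LOCUS, FEATURES and ORIGIN blocks of a single-record GenBank flat
#' file. Features of kind `gene`, `CDS`, `tRNA` and `rRNA` are captured with
#' strand and exon structure: `join(a..b,c..d)` locations become multi-exon
#' features, `complement(...)` sets strand `-1`. Locations mixing strands or
#' with non-increasing segments (trans-spliced genes such as *rps12*) are
#' retained but flagged `transSpliced` and are skipped by locus extraction.
#'
#' @param file path to a GenBank flat file, or `NULL` if `text` is given.
#' @param text optional character scalar/vector with the file contents.
#' @return an [AnnotatedGenome-class].
#' @examples
#' gb <- c("LOCUS       demo  40 bp DNA circular PLN 01-JAN-2026",
#'         "FEATURES             Location/Qualifiers",
#'         "     gene            complement(10..30)",
#'         '                     /gene="psbA"',
#'         "ORIGIN",
#'         paste("        1", paste(rep("acgtacgtac", 4), collapse = " ")),
#'         "//")
#' g <- readGenBank(text = gb)
#' genomeFeatures(g)$strand   # -1
#' @export
readGenBank <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  locusLine <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locusLine)) stop("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locusLine[1L]), "[[:space:]]+")[[1L]]
  id <- toks[2L]
  statedLen <- suppressWarnings(as.integer(toks[3L]))
  circular <- any(grepl("circular", locusLine[1L], ignore.case = TRUE))

  iFeat <- grep("^FEATURES", lines)
  iOri <- grep("^ORIGIN", lines)
  if (!length(iOri)) stop("malformed GenBank record: no ORIGIN block")
  seqLines <- lines[(iOri[1L] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(sequence)) stop("malformed GenBank record: empty sequence")
  if (!is.na(statedLen) && nchar(sequence) != statedLen)
    stop(sprintf("integrity error: LOCUS states %d bp but ORIGIN has %d",
                 statedLen, nchar(sequence)))

  featRows <- list()
  if (length(iFeat)) {
    block <- lines[(iFeat[1L] + 1L):(iOri[1L] - 1L)]
    # a new feature starts with 5 spaces + key; continuation lines are
    # indented further
    starts <- grep("^ {5}\\S", block)
    starts <- c(starts, length(block) + 1L)
    for (k in seq_len(length(starts) - 1L)) {
      chunk <- block[starts[k]:(starts[k + 1L] - 1L)]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first qualifier
      qual <- grep("^\\s+/", chunk)
      locEnd <- if (length(qual)) qual[1L] - 1L else length(chunk)
      loc <- paste(trimws(sub("^ {5}\\S+\\s*", "", chunk[1L])),
                   if (locEnd >= 2L)
                     paste(trimws(chunk[2:locEnd]), collapse = "") else "",
                   sep = "")
      name <- NA_character_
      g <- grep('^\\s+/gene="', chunk, value = TRUE)
      if (length(g)) name <- sub('.*?/gene="([^"]*)".*', "\\1", g[1L])
      if (is.na(name)) {
        g <- grep('^\\s+/(product|locus_tag)="', chunk, value = TRUE)
        if (length(g)) name <- sub('.*?="([^"]*)".*', "\\1", g[1L])
      }
      if (is.na(name)) name <- sprintf("feature%d", k)
      parsed <- tryCatch(parseGenBankLocation(loc),
                         error = function(e)
                           stop(sprintf("parse error in feature '%s': %s",
                                        name, conditionMessage(e)),
                                call. = FALSE))
      featRows[[length(featRows) + 1L]] <-
        list(name = name, kind = key, strand = parsed$strand,
             exons = parsed$exons, transSpliced = parsed$transSpliced)
    }
  }
  features <- DataFrame(
    name = vapply(featRows, `[[`, "", "name"),
    kind = vapply(featRows, `[[`, "", "kind"),
    strand = vapply(featRows, `[[`, 0L, "strand"),
    exons = IRangesList(lapply(featRows, `[[`, "exons")),
    transSpliced = vapply(featRows, `[[`, FALSE, "transSpliced"))
  bad <- which(vapply(seq_len(nrow(features)), function(i)
    max(IRanges::end(features$exons[[i]])) > nchar(sequence), FALSE))
  if (length(bad))
    stop(sprintf("integrity error: feature '%s' extends beyond the sequence",
                 features$name[bad[1L]]))
  annotatedGenome(id, sequence, circular, features)
}

# parse a GenBank location string into exons (IRanges, sorted), strand and
# a trans-spliced flag
parseGenBankLocation <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  if (!nzchar(loc)) stop("empty location")
  rec <- function(s, strand) {
    if (grepl("^complement\\(", s)) {
      inner <- stripOuter(s, "complement")
      return(rec(inner, -strand))
    }
    if (grepl("^(join|order)\\(", s)) {
      op <- sub("\\(.*$", "", s)
      inner <- stripOuter(s, op)
      parts <- splitTopLevel(inner)
      do.call(rbind, lapply(parts, rec, strand = strand))
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      se <- as.integer(strsplit(s, "..", fixed = TRUE)[[1L]])
      if (se[2L] < se[1L]) stop(sprintf("inverted interval '%s'", s))
      data.frame(start = se[1L], end = se[2L], strand = strand)
    } else if (grepl("^[0-9]+$", s)) {
      p <- as.integer(s)
      data.frame(start = p, end = p, strand = strand)
    } else stop(sprintf("unparseable location component '%s'", s))
  }
  segs <- rec(loc, +1L)
  transSpliced <- length(unique(segs$strand)) > 1L ||
    grepl("order\\(", loc) ||
    (nrow(segs) > 1L && is.unsorted(segs$start, strictly = TRUE) &&
       is.unsorted(rev(segs$start), strictly = TRUE))
  o <- order(segs$start)
  segs <- segs[o, ]
  if (nrow(segs) > 1L && any(segs$start[-1L] <= segs$end[-nrow(segs)]))
    transSpliced <- TRUE
  list(exons = IRanges(start = segs$start, end = segs$end),
       strand = as.integer(sign(sum(segs$strand))),
       transSpliced = transSpliced)
}

stripOuter <- function(s, op) {
  if (!grepl(sprintf("^%s\\(", op), s) || !endsWith(s, ")"))
    stop(sprintf("unbalanced '%s(...)' in location", op))
  substr(s, nchar(op) + 2L, nchar(s) - 1L)
}

splitTopLevel <- function(s) {
  depth <- 0L; parts <- character(); cur <- character()
  for (ch in seqChars(s)) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      parts <- c(parts, paste(cur, collapse = "")); cur <- character()
    } else cur <- c(cur, ch)
  }
  if (depth != 0L) stop("unbalanced parentheses in location")
  c(parts, paste(cur, collapse = ""))
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits LOCUS, FEATURES (with `/gene` qualifiers and `join`/`complement`
#' locations) and ORIGIN blocks readable by [readGenBank()].
#'
#' @param genome an [AnnotatedGenome-class].
#' @param file output path; when `NULL` the lines are returned invisibly.
#' @return invisibly, the character vector of file lines.
#' @export
writeGenBank <- function(genome, file = NULL) {
  seq <- as.character(genome@sequence)
  n <- nchar(seq)
  out <- c(sprintf("LOCUS       %s  %d bp    DNA     %s PLN 01-JAN-2026",
                   genome@id, n,
                   if (genome@circular) "circular" else "linear"),
           sprintf("DEFINITION  %s plastome.", genome@id),
           "FEATURES             Location/Qualifiers")
  fts <- genome@features
  for (i in seq_len(nrow(fts))) {
    ex <- fts$exons[[i]]
    segs <- sprintf("%d..%d", IRanges::start(ex), IRanges::end(ex))
    loc <- if (length(segs) > 1L)
      sprintf("join(%s)", paste(segs, collapse = ",")) else segs
    if (fts$strand[i] < 0L) loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-16s%s", fts$kind[i], loc),
             sprintf('                     /gene="%s"', fts$name[i]))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  out <- c(out, "//")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

## ---- FASTA ----------------------------------------------------------------

#' Read FASTA sequences
#'
#' Sequences are case-folded to uppercase. If all records have equal length
#' the result is a [DNAAlignment-class]; otherwise an unaligned
#' `DNAStringSet` is returned.
#'
#' @param file path to a FASTA file, or `NULL` if `text` is given.
#' @param text optional character vector with the file contents.
#' @return a [DNAAlignment-class] or `DNAStringSet`.
#' @export
readFasta <- function(file = NULL, text = NULL) {
  if (is.null(file)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  x <- readDNAStringSet(file)
  if (!length(x)) stop("FASTA file contains no records")
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence labels in FASTA input")
  if (any(width(x) == 0L)) stop("empty FASTA record")
  x <- DNAStringSet(toupper(x))
  if (length(unique(width(x))) == 1L) dnaAlignment(x) else x
}

#' Write sequences to FASTA
#'
#' @param x a `DNAStringSet`, [DNAAlignment-class] or named character vector.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeFasta <- function(x, file) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(as(x, "DNAStringSet"), file)
  invisible(file)
}

## ---- newick ---------------------------------------------------------------

#' Read a newick tree
#'
#' A thin, validating wrapper around [ape::read.tree]. Unbalanced
#' parentheses are reported with the character offset of the imbalance.
#'
#' @param file path to a newick file, or `NULL` if `text` is given.
#' @param text optional newick string.
#' @param unroot suppress a degree-2 root node (the unrooted
#'   interpretation)?
#' @return an `ape::phylo` tree.
#' @export
readNewick <- function(file = NULL, text = NULL, unroot = FALSE) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- seqChars(text)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("newick parse error: unbalanced ')' at offset %d", i))
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at end of input (offset %d)",
                 depth, nchar(text)))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL)
  if (is.null(tr)) stop("newick parse error: ", text)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in newick tree")
  if (unroot && !is.null(tr$edge)) tr <- ape::unroot(tr)
  tr
}

#' Write a tree as newick
#'
#' @param tree an `ape::phylo`.
#' @param file output path, or `NULL` to return the string.
#' @return the newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

## ---- NEXUS SPLITS ---------------------------------------------------------

#' Write a split system as a NEXUS SPLITS block
#'
#' Emits TAXA and SPLITS blocks in the dialect used by split-graph viewers
#' (SplitsTree). Split sides are written as index sets of the side not
#' containing taxon 1; weights are serialized to 12 significant digits.
#' Trivial splits missing from the system are added with weight 0 so that
#' the block always describes a complete split network.
#'
#' @param ss a [SplitSystem-class].
#' @param file output path, or `NULL` to return lines.
#' @param includeTrivial add absent trivial splits with weight 0?
#' @return invisibly, the character vector of file lines.
#' @export
writeSplitsNexus <- function(ss, file = NULL, includeTrivial = TRUE) {
  if (!nSplits(ss) && !includeTrivial) stop("empty split system")
  n <- length(ss@taxa)
  sides <- ss@splits
  weights <- ss@weights
  if (includeTrivial) {
    have <- vapply(sides, splitKey, "")
    for (i in seq_len(n)) {
      s <- canonicalSide(i, n)
      if (!splitKey(s) %in% have) {
        sides <- c(sides, list(s)); weights <- c(weights, 0)
      }
    }
  }
  if (!length(sides)) stop("empty split system")
  quoteLab <- function(x)
    ifelse(grepl("[[:space:]'()]", x), sprintf("'%s'", gsub("'", "''", x)), x)
  out <- c("#NEXUS", "", "BEGIN TAXA;",
           sprintf("DIMENSIONS NTAX=%d;", n), "TAXLABELS",
           paste0("  ", quoteLab(ss@taxa)), ";", "END;", "",
           "BEGIN SPLITS;",
           sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", n, length(sides)),
           "FORMAT LABELS=NO WEIGHTS=YES;")
  if (length(ss@circularOrder))
    out <- c(out, sprintf("CYCLE %s;", paste(ss@circularOrder, collapse = " ")))
  out <- c(out, "MATRIX")
  for (k in seq_along(sides))
    out <- c(out, sprintf("[%d]\t%.12g\t%s,", k, weights[k],
                          paste(sides[[k]], collapse = " ")))
  out <- c(out, ";", "END;")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read a NEXUS SPLITS block written by [writeSplitsNexus()]
#'
#' @param file path, or `NULL` if `text` is given.
#' @param text optional character vector of NEXUS lines.
#' @return a [SplitSystem-class].
#' @export
readSplitsNexus <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  iTax <- grep("^TAXLABELS", lines)
  if (!length(iTax)) stop("no TAXLABELS in NEXUS input")
  taxa <- character()
  for (i in (iTax[1L] + 1L):length(lines)) {
    l <- trimws(lines[i])
    if (l == ";") break
    l <- sub("^'(.*)'$", "\\1", l)
    taxa <- c(taxa, gsub("''", "'", l))
  }
  cyc <- grep("^CYCLE", lines, value = TRUE)
  circularOrder <- if (length(cyc))
    as.integer(strsplit(trimws(sub(";", "", sub("^CYCLE", "", cyc[1L]))),
                        "[[:space:]]+")[[1L]]) else integer()
  iMat <- grep("^MATRIX", lines)
  if (!length(iMat)) stop("no MATRIX in NEXUS SPLITS input")
  sides <- list(); weights <- numeric()
  for (i in (iMat[1L] + 1L):length(lines)) {
    l <- trimws(lines[i])
    if (l == ";") break
    l <- sub("^\\[[0-9]+\\]\\s*", "", l)
    l <- sub(",$", "", l)
    toks <- strsplit(l, "[[:space:]]+")[[1L]]
    weights <- c(weights, as.numeric(toks[1L]))
    sides[[length(sides) + 1L]] <- as.integer(toks[-1L])
  }
  splitSystem(taxa, sides, weights, circularOrder)
}
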