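#' @include AllClasses.R utils.R
NULL

#' Construct a typed character partition
#'
#' @param name partition label.
#' @param data taxa-by-characters matrix (rownames = taxa). Discrete types
#'   take character (or coercible) states with `"?"` for missing;
#'   continuous takes numeric with `NA` for missing.
#' @param ctype `"dna"`, `"binary"`, `"unordered"` or `"continuous"`.
#' @param gapAsState for `"dna"`: treat `-` as a fifth state (default TRUE,
#'   the usual coding for indel-informative non-coding loci)?
#' @return a [CharacterPartition-class]. Continuous characters are
#'   range-standardized so that the span between the two most dissimilar
#'   observed states costs exactly one step; characters with zero observed
#'   range are excluded with a warning.
#' @export
characterPartition <- function(name, data,
                               ctype = c("dna", "binary", "unordered",
                                         "continuous"),
                               gapAsState = TRUE) {
  ctype <- match.arg(ctype)
  if (ctype == "continuous") {
    data <- as.matrix(data)
    storage.mode(data) <- "double"
    rng <- apply(data, 2L, function(x) range(x, na.rm = TRUE))
    span <- rng[2L, ] - rng[1L, ]
    bad <- !is.finite(span) | span == 0
    if (any(bad)) {
      warning(sprintf("partition '%s': excluding %d zero-range continuous character(s)",
                      name, sum(bad)))
      data <- data[, !bad, drop = FALSE]
      rng <- rng[, !bad, drop = FALSE]
      span <- span[!bad]
    }
    std <- sweep(sweep(data, 2L, rng[1L, ]), 2L, span, "/")
    return(new("CharacterPartition", name = name, ctype = ctype,
               data = std, gapAsState = FALSE, ranges = rng))
  }
  if (is(data, "XStringSet") || (is.character(data) && is.null(dim(data))))
    data <- alignmentMatrix(data)
  m <- as.matrix(data)
  m[] <- toupper(as.character(m))
  m[is.na(m) | m == "" | m == "N"] <- "?"
  if (ctype == "dna") {
    m[!(m %in% c("A", "C", "G", "T", "-", "?"))] <- "?"
    if (!gapAsState) m[m == "-"] <- "?"
  }
  new("CharacterPartition", name = name, ctype = ctype, data = m,
      gapAsState = gapAsState && ctype == "dna",
      ranges = matrix(numeric(), 2L, 0L))
}

# state alphabet of a discrete partition
partitionAlphabet <- function(p) {
  if (p@ctype == "dna")
    return(c("A", "C", "G", "T", if (p@gapAsState) "-"))
  sort(setdiff(unique(as.character(p@data)), c("?", "-")))
}

#' Assemble a mixed character matrix for total-evidence analysis
#'
#' Partitions are row-aligned to the union of their taxa; blocks for taxa
#' absent from a partition are filled with `"?"` (discrete) or `NA`
#' (continuous), keeping the matrix rectangular. Optionally a dummy
#' outgroup row is appended, used only to polarize character change:
#' coded all-missing by default (it then adds no steps anywhere) or
#' all-primitive (state `"0"` / the observed minimum).
#'
#' @param partitions list of [CharacterPartition-class] objects (see
#'   [characterPartition()]).
#' @param dummyOutgroup append a dummy outgroup row?
#' @param outgroupCoding `"missing"` (all `"?"`) or `"primitive"`.
#' @param outgroupLabel its taxon label.
#' @return a [MixedMatrix-class].
#' @examples
#' p <- characterPartition("morpho",
#'   matrix(c("0","1","1","0"), 2, dimnames = list(c("A","B"), NULL)),
#'   ctype = "binary")
#' assembleMixedMatrix(list(p))
#' @export
assembleMixedMatrix <- function(partitions, dummyOutgroup = TRUE,
                                outgroupCoding = c("missing", "primitive"),
                                outgroupLabel = "outgroup") {
  outgroupCoding <- match.arg(outgroupCoding)
  stopifnot(length(partitions) >= 1L)
  taxa <- unique(unlist(lapply(partitions, function(p) rownames(p@data))))
  og <- NA_character_
  if (dummyOutgroup) {
    if (outgroupLabel %in% taxa)
      stop(sprintf("taxon label '%s' clashes with the dummy outgroup",
                   outgroupLabel))
    taxa <- c(taxa, outgroupLabel)
    og <- outgroupLabel
  }
  parts <- lapply(partitions, function(p) {
    isCont <- p@ctype == "continuous"
    full <- matrix(if (isCont) NA_real_ else "?", length(taxa), ncol(p@data),
                   dimnames = list(taxa, colnames(p@data)))
    full[rownames(p@data), ] <- p@data
    if (dummyOutgroup && outgroupCoding == "primitive")
      full[og, ] <- if (isCont) 0 else "0"
    methods::initialize(p, data = full)
  })
  new("MixedMatrix", taxa = taxa, partitions = parts, outgroup = og)
}

#' Read a mixed character matrix from a relaxed CSV file
#'
#' The CSV holds one row per taxon (first column = taxon label) and one
#' column per character; `typeMap` assigns consecutive column blocks to
#' typed partitions.
#'
#' @param file CSV path.
#' @param typeMap data.frame with columns `name`, `ctype`, `ncolumns`
#'   describing consecutive blocks left to right.
#' @param ... passed to [assembleMixedMatrix()].
#' @return a [MixedMatrix-class].
#' @export
readMixedCsv <- function(file, typeMap, ...) {
  raw <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  if (sum(typeMap$ncolumns) != ncol(body))
    stop("typeMap column counts do not tile the CSV")
  at <- 0L
  parts <- vector("list", nrow(typeMap))
  for (i in seq_len(nrow(typeMap))) {
    cols <- (at + 1L):(at + typeMap$ncolumns[i])
    at <- at + typeMap$ncolumns[i]
    block <- as.matrix(body[, cols, drop = FALSE])
    rownames(block) <- taxa
    parts[[i]] <- characterPartition(typeMap$name[i], block,
                                     ctype = typeMap$ctype[i])
  }
  assembleMixedMatrix(parts, ...)
}

# restrict a MixedMatrix to a taxon subset (order preserved)
subsetTaxa <- function(mm, taxa) {
  parts <- lapply(mm@partitions, function(p)
    methods::initialize(p, data = p@data[taxa, , drop = FALSE]))
  og <- if (!is.na(mm@outgroup) && mm@outgroup %in% taxa) mm@outgroup
        else NA_character_
  new("MixedMatrix", taxa = taxa, partitions = parts, outgroup = og)
}

# subset characters (global column units) of a MixedMatrix; `units` is an
# integer vector over the concatenated columns, duplicates allowed
# (bootstrap)
subsetCharacters <- function(mm, units) {
  widths <- vapply(mm@partitions, function(p) ncol(p@data), 0L)
  offs <- cumsum(c(0L, widths[-length(widths)]))
  parts <- list()
  for (k in seq_along(mm@partitions)) {
    local <- units[units > offs[k] & units <= offs[k] + widths[k]] - offs[k]
    if (!length(local)) next
    p <- mm@partitions[[k]]
    parts[[length(parts) + 1L]] <-
      methods::initialize(p, data = p@data[, local, drop = FALSE],
                          ranges = if (p@ctype == "continuous")
                            p@ranges[, local, drop = FALSE] else p@ranges)
  }
  if (!length(parts)) {
    empty <- matrix("?", length(mm@taxa), 0L,
                    dimnames = list(mm@taxa, NULL))
    parts <- list(new("CharacterPartition", name = "empty", ctype = "binary",
                      data = empty, gapAsState = FALSE,
                      ranges = matrix(numeric(), 2L, 0L)))
  }
  new("MixedMatrix", taxa = mm@taxa, partitions = parts,
      outgroup = mm@outgroup)
}

# total number of character columns
nCharacters <- function(mm)
  sum(vapply(mm@partitions, function(p) ncol(p@data), 0L))
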