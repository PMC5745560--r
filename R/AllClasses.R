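#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges IRangesList
#' @importFrom Biostrings DNAString DNAStringSet BStringSet width
NULL

#' Multiple sequence alignment of DNA
#'
#' A thin wrapper around [Biostrings::DNAStringSet] that guarantees the
#' invariants of an alignment: at least one row, all rows of equal width,
#' and unique, non-empty row (taxon) names. Gap (`-`) and IUPAC ambiguity
#' letters are allowed; statistics downstream treat non-ACGT letters as
#' missing.
#'
#' @slot .Data inherited from `DNAStringSet`.
#' @seealso [dnaAlignment()], [readFasta()]
#' @export
setClass("DNAAlignment", contains = "DNAStringSet")

setValidity("DNAAlignment", function(object) {
  if (length(object) < 1L) return("alignment must contain at least one row")
  if (length(unique(width(object))) != 1L)
    return("all alignment rows must have equal length")
  nm <- names(object)
  if (is.null(nm) || any(!nzchar(nm))) return("all rows must be named")
  if (anyDuplicated(nm)) return("taxon labels must be unique")
  TRUE
})

#' Construct a DNAAlignment
#'
#' @param x a named `DNAStringSet`, a named character vector of equal-length
#'   gapped sequences, or anything `DNAStringSet()` accepts.
#' @return a [DNAAlignment-class] object.
#' @examples
#' aln <- dnaAlignment(c(A = "ACGT", B = "ACGA"))
#' @export
dnaAlignment <- function(x) {
  if (is.character(x)) x <- DNAStringSet(toupper(x))
  new("DNAAlignment", as(x, "DNAStringSet"))
}

#' Annotated (plastid) genome
#'
#' A circular or linear DNA sequence together with its gene-level features.
#' Features live in a [S4Vectors::DataFrame] with columns `name` (gene
#' symbol), `kind` (`gene`, `CDS`, `tRNA` or `rRNA`), `strand` (`+1L`/`-1L`),
#' `exons` (an [IRanges::IRangesList], 1-based inclusive coordinates on the
#' forward strand, sorted and non-overlapping within a feature) and
#' `transSpliced` (features with trans-spliced locations are retained but
#' flagged non-extractable).
#'
#' @slot id taxon or accession label.
#' @slot sequence a `DNAString` (uppercase A/C/G/T/N).
#' @slot circular logical scalar.
#' @slot features a `DataFrame`, see above.
#' @seealso [annotatedGenome()], [readGenBank()], [extractNoncoding()]
#' @export
setClass("AnnotatedGenome",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical", features = "DataFrame"))

setValidity("AnnotatedGenome", function(object) {
  if (length(object@sequence) < 1L) return("sequence must be non-empty")
  need <- c("name", "kind", "strand", "exons", "transSpliced")
  if (!all(need %in% colnames(object@features)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  L <- length(object@sequence)
  for (i in seq_len(nrow(object@features))) {
    ex <- object@features$exons[[i]]
    if (length(ex) < 1L)
      return(sprintf("feature '%s' has no exons", object@features$name[i]))
    st <- IRanges::start(ex); en <- IRanges::end(ex)
    if (any(st < 1L) || any(en > L))
      return(sprintf("feature '%s' lies outside the sequence",
                     object@features$name[i]))
    if (is.unsorted(st, strictly = TRUE) && length(st) > 1L)
      return(sprintf("exons of '%s' must be sorted by start",
                     object@features$name[i]))
    if (length(st) > 1L && any(st[-1L] <= en[-length(en)]))
      return(sprintf("exons of '%s' overlap", object@features$name[i]))
  }
  TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param id taxon/accession label.
#' @param sequence `DNAString` or character scalar.
#' @param circular logical, is the molecule circular?
#' @param features a `DataFrame`/`data.frame` with columns `name`, `kind`,
#'   `strand`, `exons` (list of `IRanges`), optional `transSpliced`;
#'   or NULL for none.
#' @return an [AnnotatedGenome-class].
#' @export
annotatedGenome <- function(id, sequence, circular = TRUE, features = NULL) {
  if (is.character(sequence)) sequence <- DNAString(toupper(sequence))
  if (is.null(features)) {
    features <- DataFrame(name = character(), kind = character(),
                          strand = integer(),
                          exons = IRangesList(),
                          transSpliced = logical())
  } else {
    features <- as(features, "DataFrame")
    if (!"transSpliced" %in% colnames(features))
      features$transSpliced <- rep(FALSE, nrow(features))
    if (!is(features$exons, "IRangesList"))
      features$exons <- IRangesList(as.list(features$exons))
    features$strand <- as.integer(features$strand)
  }
  new("AnnotatedGenome", id = as.character(id), sequence = sequence,
      circular = isTRUE(circular), features = features)
}

#' Homologous copies of one locus across genomes
#'
#' @slot locusId canonical locus name (e.g. `"trnH-psbA"`, `"clpP_intron1"`).
#' @slot members `DNAStringSet` named by genome id, one sequence per carrier.
#' @slot absent genome ids in which the locus could not be resolved.
#' @slot duplicated genome ids in which more than one copy was found (the
#'   first copy by coordinate is kept in `members`).
#' @seealso [harvestLocus()]
#' @export
setClass("LocusSet",
  representation(locusId = "character", members = "DNAStringSet",
                 absent = "character", duplicated = "character"))

setValidity("LocusSet", function(object) {
  if (anyDuplicated(names(object@members)))
    return("one sequence per genome is required")
  TRUE
})

#' Weighted split system
#'
#' A collection of weighted bipartitions (splits) of a fixed taxon set.
#' Each split is stored canonically as the sorted integer index set of the
#' side NOT containing the first taxon. When produced by [neighborNet()],
#' `circularOrder` holds the circular taxon ordering and every split is an
#' interval of it; supernetwork systems leave it empty.
#'
#' @slot taxa character vector of taxon labels.
#' @slot splits list of sorted integer vectors (canonical sides).
#' @slot weights nonnegative numeric, parallel to `splits`.
#' @slot circularOrder integer permutation of `seq_along(taxa)`, or
#'   `integer(0)`.
#' @seealso [splitSystem()], [neighborNet()], [zclosureSupernetwork()]
#' @export
setClass("SplitSystem",
  representation(taxa = "character", splits = "list", weights = "numeric",
                 circularOrder = "integer"))

setValidity("SplitSystem", function(object) {
  n <- length(object@taxa)
  if (n < 2L) return("at least two taxa required")
  if (anyDuplicated(object@taxa)) return("taxon labels must be unique")
  if (length(object@splits) != length(object@weights))
    return("splits and weights must be parallel")
  if (any(object@weights < 0)) return("split weights must be nonnegative")
  for (s in object@splits) {
    if (length(s) < 1L || length(s) >= n)
      return("split sides must be non-empty proper subsets")
    if (1L %in% s) return("canonical split side must exclude taxon 1")
    if (is.unsorted(s, strictly = TRUE)) return("split sides must be sorted")
    if (any(s < 1L) || any(s > n)) return("split side out of taxon range")
  }
  keys <- vapply(object@splits, paste, "", collapse = ",")
  if (anyDuplicated(keys)) return("duplicate splits")
  ord <- object@circularOrder
  if (length(ord)) {
    if (!setequal(ord, seq_len(n))) return("circularOrder must be a permutation")
    pos <- integer(n); pos[ord] <- seq_len(n)
    for (s in object@splits) {
      if (!.isCircularInterval(pos[s], n))
        return("every split must be an interval of circularOrder")
    }
  }
  TRUE
})

# is a set of positions (on a cycle 1..n) a contiguous arc?
# true iff the set or its complement is a contiguous linear run
.isCircularInterval <- function(pos, n) {
  contiguous <- function(p) {
    p <- sort(p)
    length(p) == 0L || p[length(p)] - p[1L] == length(p) - 1L
  }
  contiguous(pos) || contiguous(setdiff(seq_len(n), pos))
}

#' Construct a SplitSystem
#'
#' Sides may be given as taxon labels or integer indices; they are
#' canonicalized (complemented if they contain the first taxon, sorted) and
#' duplicate splits have their weights summed.
#'
#' @param taxa character vector of taxon labels.
#' @param sides list of character or integer vectors, one side per split.
#' @param weights numeric weights (default 1 per split).
#' @param circularOrder optional integer permutation or character vector of
#'   labels giving the circular taxon ordering.
#' @return a [SplitSystem-class].
#' @export
splitSystem <- function(taxa, sides = list(), weights = rep(1, length(sides)),
                        circularOrder = integer()) {
  n <- length(taxa)
  canon <- vector("list", length(sides))
  for (i in seq_along(sides)) {
    s <- sides[[i]]
    if (is.character(s)) s <- match(s, taxa)
    if (anyNA(s)) stop("unknown taxon in split side")
    s <- sort(unique(as.integer(s)))
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    canon[[i]] <- s
  }
  keys <- vapply(canon, paste, "", collapse = ",")
  if (anyDuplicated(keys)) {
    w <- tapply(weights, keys, sum)
    keep <- !duplicated(keys)
    canon <- canon[keep]
    weights <- as.numeric(w[vapply(canon, paste, "", collapse = ",")])
  }
  if (is.character(circularOrder)) circularOrder <- match(circularOrder, taxa)
  new("SplitSystem", taxa = as.character(taxa), splits = canon,
      weights = as.numeric(weights),
      circularOrder = as.integer(circularOrder))
}

#' Concatenated multilocus supermatrix
#'
#' @slot alignment `BStringSet` (rows may contain the fill character `?` for
#'   absent taxon-by-partition blocks).
#' @slot partitions data.frame with columns `locus`, `start`, `end`
#'   (1-based inclusive column spans).
#' @slot missingFraction proportion of cells that are missing under the
#'   configured accounting.
#' @slot fill single fill character used for absent blocks.
#' @seealso [concatenatePartitions()]
#' @export
setClass("Supermatrix",
  representation(alignment = "BStringSet", partitions = "data.frame",
                 missingFraction = "numeric", fill = "character"))

setValidity("Supermatrix", function(object) {
  if (nrow(object@partitions) < 1L) return("at least one partition required")
  w <- sum(object@partitions$end - object@partitions$start + 1L)
  if (length(object@alignment) && w != width(object@alignment)[1L])
    return("partition spans must tile the matrix")
  if (object@missingFraction < 0 || object@missingFraction > 1)
    return("missingFraction must lie in [0, 1]")
  TRUE
})

#' One typed partition of a mixed character matrix
#'
#' @slot name partition label.
#' @slot ctype one of `"dna"`, `"binary"`, `"unordered"`, `"continuous"`.
#' @slot data taxa-by-characters matrix; character states (with `"?"` for
#'   missing) for discrete types, numeric (standardized, `NA` missing) for
#'   continuous.
#' @slot gapAsState for `"dna"`: treat `-` as a fifth state?
#' @slot ranges for `"continuous"`: 2-by-ncol matrix of the observed raw
#'   range of each character before standardization.
#' @export
setClass("CharacterPartition",
  representation(name = "character", ctype = "character", data = "matrix",
                 gapAsState = "logical", ranges = "matrix"))

setValidity("CharacterPartition", function(object) {
  if (!object@ctype %in% c("dna", "binary", "unordered", "continuous"))
    return("unknown ctype")
  if (object@ctype == "continuous") {
    if (!is.numeric(object@data)) return("continuous data must be numeric")
  } else if (!is.character(object@data)) {
    return("discrete data must be character")
  }
  if (is.null(rownames(object@data))) return("data must have taxon rownames")
  TRUE
})

#' Partitioned mixed character matrix for total-evidence parsimony
#'
#' Taxa-by-characters data split into typed partitions
#' ([CharacterPartition-class]). All partitions share the same taxon rows
#' (rectangularity is enforced by [assembleMixedMatrix()], which fills
#' missing blocks with `"?"`/`NA`). An optional dummy outgroup row is used
#' only to polarize character changes.
#'
#' @slot taxa character vector (row order of every partition).
#' @slot partitions list of [CharacterPartition-class] objects.
#' @slot outgroup label of the dummy outgroup taxon, or `NA_character_`.
#' @seealso [assembleMixedMatrix()], [exactSearch()], [mapSynapomorphies()]
#' @export
setClass("MixedMatrix",
  representation(taxa = "character", partitions = "list",
                 outgroup = "character"))

setValidity("MixedMatrix", function(object) {
  if (anyDuplicated(object@taxa)) return("duplicated taxon labels")
  for (p in object@partitions) {
    if (!is(p, "CharacterPartition")) return("partitions must be CharacterPartition")
    if (!identical(rownames(p@data), object@taxa))
      return(sprintf("partition '%s' rows do not match taxa", p@name))
  }
  if (!is.na(object@outgroup) && !object@outgroup %in% object@taxa)
    return("outgroup must be one of the taxa")
  TRUE
})
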