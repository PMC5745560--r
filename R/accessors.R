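#' @include AllClasses.R
NULL

#' Accessors for plastophylo classes
#'
#' Small generic accessors; prefer these over direct slot access.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))
#' @rdname accessors
#' @export
setMethod("taxonNames", "DNAAlignment", function(x) names(x))
#' @rdname accessors
#' @export
setMethod("taxonNames", "SplitSystem", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("taxonNames", "MixedMatrix", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("taxonNames", "Supermatrix", function(x) names(x@alignment))

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setMethod("genomeId", "AnnotatedGenome", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setMethod("genomeSequence", "AnnotatedGenome", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname accessors
#' @export
setMethod("genomeFeatures", "AnnotatedGenome", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @rdname accessors
#' @export
setMethod("isCircularGenome", "AnnotatedGenome", function(x) x@circular)

#' @rdname accessors
#' @export
setGeneric("splitSides", function(x) standardGeneric("splitSides"))
#' @rdname accessors
#' @export
setMethod("splitSides", "SplitSystem", function(x) x@splits)

#' @rdname accessors
#' @export
setGeneric("splitWeights", function(x) standardGeneric("splitWeights"))
#' @rdname accessors
#' @export
setMethod("splitWeights", "SplitSystem", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("circularOrder", function(x) standardGeneric("circularOrder"))
#' @rdname accessors
#' @export
setMethod("circularOrder", "SplitSystem", function(x) x@circularOrder)

#' @rdname accessors
#' @export
setGeneric("nSplits", function(x) standardGeneric("nSplits"))
#' @rdname accessors
#' @export
setMethod("nSplits", "SplitSystem", function(x) length(x@splits))

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setMethod("locusId", "LocusSet", function(x) x@locusId)

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setMethod("members", "LocusSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("absentFrom", function(x) standardGeneric("absentFrom"))
#' @rdname accessors
#' @export
setMethod("absentFrom", "LocusSet", function(x) x@absent)

#' @rdname accessors
#' @export
setGeneric("partitionTable", function(x) standardGeneric("partitionTable"))
#' @rdname accessors
#' @export
setMethod("partitionTable", "Supermatrix", function(x) x@partitions)
#' @rdname accessors
#' @export
setMethod("partitionTable", "MixedMatrix", function(x) {
  data.frame(name = vapply(x@partitions, slot, "", "name"),
             ctype = vapply(x@partitions, slot, "", "ctype"),
             ncolumns = vapply(x@partitions, function(p) ncol(p@data), 0L))
})

#' @rdname accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))
#' @rdname accessors
#' @export
setMethod("missingFraction", "Supermatrix", function(x) x@missingFraction)

#' @rdname accessors
#' @export
setGeneric("superAlignment", function(x) standardGeneric("superAlignment"))
#' @rdname accessors
#' @export
setMethod("superAlignment", "Supermatrix", function(x) x@alignment)

## show methods -------------------------------------------------------------

setMethod("show", "AnnotatedGenome", function(object) {
  cat(sprintf("AnnotatedGenome '%s': %d bp, %s, %d features\n",
              object@id, length(object@sequence),
              if (object@circular) "circular" else "linear",
              nrow(object@features)))
  kinds <- table(object@features$kind)
  if (length(kinds))
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "DNAAlignment", function(object) {
  cat(sprintf("DNAAlignment: %d taxa x %d columns\n",
              length(object), width(object)[1L]))
  callNextMethod()
})

setMethod("show", "SplitSystem", function(object) {
  cat(sprintf("SplitSystem on %d taxa: %d splits (%d non-trivial)%s\n",
              length(object@taxa), length(object@splits),
              sum(vapply(object@splits, length, 0L) > 1L &
                  vapply(object@splits, length, 0L) < length(object@taxa) - 1L),
              if (length(object@circularOrder)) ", circular" else ""))
})

setMethod("show", "LocusSet", function(object) {
  cat(sprintf("LocusSet '%s': %d members", object@locusId,
              length(object@members)))
  if (length(object@absent))
    cat(sprintf(", absent from: %s", paste(object@absent, collapse = ", ")))
  if (length(object@duplicated))
    cat(sprintf(", duplicated in: %s", paste(object@duplicated, collapse = ", ")))
  cat("\n")
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf(
    "Supermatrix: %d taxa x %d columns, %d partitions, %.2f%% missing\n",
    length(object@alignment),
    if (length(object@alignment)) width(object@alignment)[1L] else 0L,
    nrow(object@partitions), 100 * object@missingFraction))
})

setMethod("show", "MixedMatrix", function(object) {
  tab <- partitionTable(object)
  cat(sprintf("MixedMatrix: %d taxa, %d partitions, %d characters%s\n",
              length(object@taxa), nrow(tab), sum(tab$ncolumns),
              if (!is.na(object@outgroup))
                sprintf(" (outgroup: %s)", object@outgroup) else ""))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %-10s %d\n", tab$name[i], tab$ctype[i],
                tab$ncolumns[i]))
})

setMethod("show", "CharacterPartition", function(object) {
  cat(sprintf("CharacterPartition '%s' (%s): %d taxa x %d characters\n",
              object@name, object@ctype, nrow(object@data), ncol(object@data)))
})
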