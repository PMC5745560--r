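#' @include AllClasses.R utils.R parsimony.R
NULL

#' Bootstrap / jackknife clade support for exact parsimony
#'
#' Characters (all columns of all partitions, continuous characters as
#' single resampling units like any other column) are resampled
#' `reps` times: the bootstrap samples columns with replacement, the
#' jackknife deletes each column independently with probability `p`
#' (0.36 emulates the classical e^-1 deletion fraction). Each replicate
#' is analysed with [exactSearch()] and a clade is counted as supported
#' when the strict consensus of the replicate's most-parsimonious trees
#' contains it.
#'
#' @param mm a [MixedMatrix-class] small enough for exact search.
#' @param method `"jackknife"` or `"bootstrap"`.
#' @param p jackknife deletion probability (ignored for bootstrap).
#' @param reps number of pseudoreplicates (>= 1).
#' @param seed integer seed; results are reproducible given the seed.
#' @param maxTaxa passed to [exactSearch()].
#' @return a data.frame of class `"supportReport"`: one row per
#'   non-trivial clade of the strict consensus of the full-matrix MP
#'   trees, with `clade` (sorted comma-joined taxa) and `support`
#'   (percent of replicates).
#' @export
resampleSupport <- function(mm, method = c("jackknife", "bootstrap"),
                            p = 0.36, reps = 1000L, seed = NULL,
                            maxTaxa = 14L) {
  method <- match.arg(method)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be at least 1")
  ref <- exactSearch(mm, maxTaxa = maxTaxa)
  refKeys <- vapply(ref$consensusSides, splitKey, "")
  if (!length(refKeys))
    return(structure(data.frame(clade = character(), support = numeric()),
                     class = c("supportReport", "data.frame")))
  counts <- setNames(numeric(length(refKeys)), refKeys)
  N <- nCharacters(mm)
  ctx <- prepareScoring(mm)
  ord <- additionOrder(mm)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      units <- if (method == "bootstrap")
        sample.int(N, N, replace = TRUE) else which(runif(N) >= p)
      core <- searchCore(ctxSubset(ctx, units), ord)
      keys <- Reduce(intersect,
                     lapply(core$found, edgeSideKeys, n = length(mm@taxa)))
      hit <- refKeys %in% keys
      counts[hit] <- counts[hit] + 1
    }
  })
  clades <- vapply(ref$consensusSides, function(s)
    paste(sort(mm@taxa[s]), collapse = ","), "")
  out <- data.frame(clade = clades, support = 100 * counts / reps)
  rownames(out) <- NULL
  class(out) <- c("supportReport", "data.frame")
  out
}
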