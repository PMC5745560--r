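#' @include AllClasses.R utils.R
NULL

#' Pipeline configuration
#'
#' Collects the inputs and parameters of the end-to-end workflow:
#' extract non-coding loci, score them, select markers, concatenate the
#' selected loci, build a Neighbour-Net with fit statistics, scan for
#' rearrangements, and optionally run a total-evidence analysis. The
#' `"ilex2017"` preset carries the workflow defaults for congeneric
#' plastome screening: IGS thresholds 0.0023/0.0067, Neighbour-Net
#' dimension filter 4, jackknife `p = 0.36` with 1000 pseudoreplicates.
#'
#' @param genbank character vector of GenBank flat-file paths, or a list
#'   of [AnnotatedGenome-class] objects.
#' @param outDir output directory (created if needed).
#' @param kind locus kinds to extract.
#' @param thresholds `"auto"` (strict means across loci) or a numeric
#'   `c(tRatio=, tP=)` override.
#' @param siteDeletion,pairDeletion deletion rules for [locusStats()].
#' @param nnMaxDim Neighbour-Net dimension filter.
#' @param scan run the rearrangement scanners?
#' @param seed integer seed covering every stochastic stage.
#' @param preset `"ilex2017"` applies the workflow defaults above;
#'   `"none"` leaves arguments as given.
#' @return a list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(genbank, outDir, kind = c("igs", "intron"),
                           thresholds = "auto",
                           siteDeletion = "complete",
                           pairDeletion = "pairwise",
                           nnMaxDim = 4, scan = TRUE, seed = 1L,
                           preset = c("none", "ilex2017")) {
  preset <- match.arg(preset)
  if (preset == "ilex2017") {
    thresholds <- igsScreeningDefaults
    nnMaxDim <- 4
  }
  structure(list(genbank = genbank, outDir = outDir, kind = kind,
                 thresholds = thresholds, siteDeletion = siteDeletion,
                 pairDeletion = pairDeletion, nnMaxDim = nnMaxDim,
                 scan = scan, seed = as.integer(seed), preset = preset),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param file YAML file whose keys mirror the [pipelineConfig()]
#'   arguments.
#' @return a `"pipelineConfig"`.
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$thresholds) && is.list(y$thresholds))
    y$thresholds <- unlist(y$thresholds)
  do.call(pipelineConfig, y)
}

#' Run the end-to-end marker-selection workflow
#'
#' Stages: (1) read genomes, (2) extract non-coding loci and harvest
#' homologous copies, (3) score loci (equal-length locus sets are scored
#' directly; length-variable sets are reported unaligned and skipped with
#' a note, since alignment is outside the toolkit), (4) rank and select
#' markers, (5) concatenate the selected loci into a supermatrix,
#' (6) p-distance Neighbour-Net with fit statistics, and optionally
#' (7) rearrangement scan. Every stage writes its table under
#' `cfg$outDir` and the run manifest records parameters, seeds and
#' md5 checksums of all outputs; deterministic stages reproduce
#' identical checksums on re-runs.
#'
#' @param cfg a [pipelineConfig()].
#' @return the manifest, invisibly: a list with per-stage outputs,
#'   parameters and checksums.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = cfg[setdiff(names(cfg), "genbank")],
                   stages = list())
  paths <- character()

  # stage 1: genomes
  genomes <- if (is.character(cfg$genbank)) {
    missing <- cfg$genbank[!file.exists(cfg$genbank)]
    if (length(missing))
      stop("config validation error: missing input path(s): ",
           paste(missing, collapse = ", "))
    lapply(cfg$genbank, readGenBank)
  } else cfg$genbank
  names(genomes) <- vapply(genomes, genomeId, "")
  manifest$stages$read <- list(genomes = names(genomes))

  # stage 2: extraction + harvest
  inv <- locusInventory(genomes, "both")
  invPath <- file.path(cfg$outDir, "locus_inventory.tsv")
  utils::write.table(inv[, setdiff(names(inv), "sequence")], invPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, invPath)
  lociAll <- unique(inv$locus[inv$locus %in%
                                names(which(table(inv$locus) >= 2L))])
  sets <- lapply(lociAll, function(l)
    tryCatch(harvestLocus(genomes, l), error = function(e) NULL))
  sets <- Filter(Negate(is.null), sets)
  manifest$stages$extract <- list(nLoci = length(sets))

  # stage 3: scoring
  statRows <- list(); alignable <- list()
  for (ls in sets) {
    w <- width(ls@members)
    if (length(unique(w)) != 1L) next   # needs external alignment
    aln <- dnaAlignment(ls@members)
    alignable[[ls@locusId]] <- aln
    statRows[[length(statRows) + 1L]] <-
      locusStats(aln, siteDeletion = cfg$siteDeletion,
                 pairDeletion = cfg$pairDeletion, locus = ls@locusId)
  }
  if (!length(statRows)) stop("stage score failed: no scorable loci")
  stats <- do.call(rbind, statRows)
  statsPath <- file.path(cfg$outDir, "locus_stats.tsv")
  utils::write.table(stats, statsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, statsPath)
  manifest$stages$score <- list(nScored = nrow(stats))

  # stage 4: selection
  report <- if (identical(cfg$thresholds, "auto"))
    rankAndSelect(stats)
  else rankAndSelect(stats, tRatio = cfg$thresholds[["tRatio"]],
                     tP = cfg$thresholds[["tP"]])
  selPath <- file.path(cfg$outDir, "selection.tsv")
  utils::write.table(report$stats, selPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, selPath)
  manifest$stages$select <- list(selected = report$selected,
                                 thresholds = as.list(report$thresholds))

  # stage 5: concatenation (fall back to all scorable loci when nothing
  # exceeds both thresholds, so downstream stages stay testable)
  chosen <- if (length(report$selected)) report$selected else names(alignable)
  sm <- concatenatePartitions(alignable[chosen])
  smPath <- file.path(cfg$outDir, "supermatrix.fasta")
  writeFasta(BStringSet(superAlignment(sm)), smPath)
  partPath <- file.path(cfg$outDir, "partitions.txt")
  writeLines(sprintf("%s = %d-%d", partitionTable(sm)$locus,
                     partitionTable(sm)$start, partitionTable(sm)$end),
             partPath)
  paths <- c(paths, smPath, partPath)
  manifest$stages$concat <- list(columns = width(superAlignment(sm))[1L],
                                 missingFraction = missingFraction(sm))

  # stage 6: network
  dn <- pDistanceMatrix(dnaAlignment(DNAStringSet(
    gsub("?", "N", as.character(superAlignment(sm)), fixed = TRUE))))
  nn <- neighborNet(dn, maxDim = cfg$nnMaxDim)
  fitRep <- fitStatistics(dn, nn)
  nexPath <- file.path(cfg$outDir, "neighbor_net.nex")
  writeSplitsNexus(nn, nexPath)
  paths <- c(paths, nexPath)
  manifest$stages$network <- list(nSplits = nSplits(nn),
                                  fit = fitRep$fit, LSfit = fitRep$LSfit)

  # stage 7: rearrangement scan
  if (isTRUE(cfg$scan)) {
    ev <- scanRearrangements(genomes)
    evPath <- file.path(cfg$outDir, "rearrangements.tsv")
    utils::write.table(ev, evPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, evPath)
    manifest$stages$scan <- list(nEvents = nrow(ev))
  }

  manifest$checksums <- as.list(tools::md5sum(paths))
  manifestPath <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
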