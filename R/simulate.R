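#' @include AllClasses.R utils.R mixed-matrix.R
NULL

#' Default plastome template for the simulator
#'
#' A desk-scale plastome proxy: 12 genes (two of them multi-exon, so that
#' intron loci exist) with realistic plastid gene names, separated by
#' intergenic spacers, on a 20 kb circle. The template defines the exact
#' gene map from which the simulator derives its ground-truth locus table.
#'
#' @return a list with `genes` (data.frame: `name`, `kind`, `strand`,
#'   `exonLens`, `intronLens`, `gapBefore`) and `genomeLength`.
#' @export
plastomeTemplate <- function() {
  genes <- data.frame(
    name = c("trnH", "psbA", "matK", "rps16", "psbK", "atpA",
             "atpF", "rpoB", "trnC", "petN", "psbM", "rbcL"),
    kind = c("tRNA", "gene", "gene", "gene", "gene", "gene",
             "gene", "gene", "tRNA", "gene", "gene", "gene"),
    strand = c(1L, -1L, 1L, -1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L, 1L),
    gapBefore = c(400L, 700L, 560L, 800L, 440L, 620L,
                  360L, 840L, 520L, 660L, 480L, 760L))
  genes$exonLens <- list(75L, 1062L, 1497L, c(227L, 40L), 186L, 1524L,
                         c(410L, 145L), 2100L, 71L, 90L, 105L, 1428L)
  genes$intronLens <- list(integer(), integer(), integer(), 880L, integer(),
                           integer(), 695L, integer(), integer(), integer(),
                           integer(), integer())
  list(genes = genes, genomeLength = 20000L)
}

# features + ground-truth locus table implied by a template, by direct
# cumulative arithmetic (kept independent of the extraction module, so it
# can serve as its oracle)
templateLayout <- function(template) {
  g <- template$genes
  pos <- 0L
  feats <- list(); loci <- list()
  spanStart <- spanEnd <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    igsStart <- pos + 1L
    pos <- pos + g$gapBefore[i]
    if (i > 1L)
      loci[[length(loci) + 1L]] <- data.frame(
        locus = sprintf("%s-%s", g$name[i - 1L], g$name[i]),
        kind = "igs", start = igsStart, end = pos)
    ex <- g$exonLens[[i]]; intr <- g$intronLens[[i]]
    st <- en <- integer(length(ex))
    spanStart[i] <- pos + 1L
    for (k in seq_along(ex)) {
      st[k] <- pos + 1L
      en[k] <- pos + ex[k]
      pos <- en[k]
      if (k < length(ex)) {
        nIntron <- length(ex) - 1L
        num <- if (g$strand[i] < 0L) nIntron - k + 1L else k
        loci[[length(loci) + 1L]] <- data.frame(
          locus = sprintf("%s_intron%d", g$name[i], num),
          kind = "intron", start = pos + 1L, end = pos + intr[k])
        pos <- pos + intr[k]
      }
    }
    spanEnd[i] <- pos
    feats[[i]] <- list(name = g$name[i], kind = g$kind[i],
                       strand = g$strand[i], exons = IRanges(st, en))
  }
  L <- template$genomeLength
  if (pos > L) stop("template does not fit the stated genome length")
  # wrap-around spacer from the last gene back to the first
  loci[[length(loci) + 1L]] <- data.frame(
    locus = sprintf("%s-%s", g$name[nrow(g)], g$name[1L]),
    kind = "igs", start = pos + 1L, end = L + g$gapBefore[1L])
  features <- DataFrame(
    name = vapply(feats, `[[`, "", "name"),
    kind = vapply(feats, `[[`, "", "kind"),
    strand = vapply(feats, `[[`, 0L, "strand"),
    exons = IRangesList(lapply(feats, `[[`, "exons")),
    transSpliced = rep(FALSE, length(feats)))
  list(features = features, loci = do.call(rbind, loci), length = L)
}

#' Simulation configuration
#'
#' @param tree an `ape::phylo`, a newick string, or an integer (a random
#'   tree with that many tips is drawn under the seed).
#' @param model substitution model: `"JC"`, `"K2P"` or `"HKY"`.
#' @param kappa transition/transversion rate ratio (K2P/HKY).
#' @param baseFreqs equilibrium base frequencies A,C,G,T (HKY).
#' @param template genome template, see [plastomeTemplate()].
#' @param treeDepth when the tree is drawn randomly (integer `tree`),
#'   rescale it so the mean root-to-tip path equals this many expected
#'   substitutions per site. The default 0.005 emulates congeneric
#'   plastomes, whose pairwise identity is around 99 percent. Trees
#'   passed explicitly keep their branch lengths (`NA` disables
#'   rescaling for random trees too).
#' @param seed integer seed; all randomness is derived from it.
#' @return a list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(tree = 6L, model = c("JC", "K2P", "HKY"),
                             kappa = 2, baseFreqs = rep(0.25, 4),
                             template = plastomeTemplate(),
                             treeDepth = 0.005, seed = 1L) {
  model <- match.arg(model)
  stopifnot(abs(sum(baseFreqs) - 1) < 1e-8, all(baseFreqs > 0))
  structure(list(tree = tree, model = model, kappa = kappa,
                 baseFreqs = baseFreqs, template = template,
                 treeDepth = treeDepth, seed = as.integer(seed)),
            class = "simulationConfig")
}

# transition probability matrix for branch length t (expected
# substitutions per site)
substitutionMatrix <- function(model, t, kappa = 2, freqs = rep(0.25, 4)) {
  if (model == "JC") {
    p <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    q <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
    P <- matrix(q, 4, 4); diag(P) <- p
    return(P)
  }
  # rate matrix with transitions (A<->G, C<->T) scaled by kappa
  ti <- matrix(c(0, 0, 1, 0,  0, 0, 0, 1,  1, 0, 0, 0,  0, 1, 0, 0), 4, 4)
  Q <- matrix(1, 4, 4) + (kappa - 1) * ti
  if (model == "HKY") Q <- sweep(Q, 2L, freqs, "*") * 4
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi0 <- if (model == "HKY") freqs else rep(0.25, 4)
  Q <- Q / sum(-diag(Q) * pi0)   # mean rate 1
  eig <- eigen(Q)
  P <- Re(eig$vectors %*% diag(exp(eig$values * t)) %*% solve(eig$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an annotated plastome set along a known tree
#'
#' Builds a root genome from the template, evolves it site-independently
#' along the tree under the configured substitution model (indels arise
#' only via [injectEvents()], keeping ground truth exact), and returns the
#' genomes together with truth tables sufficient to score every
#' downstream module.
#'
#' @param cfg a [simulationConfig()].
#' @return a list: `genomes` (named list of [AnnotatedGenome-class]),
#'   `tree` (`ape::phylo` with branch lengths), `loci` (ground-truth
#'   non-coding locus table derived from the template by direct
#'   arithmetic), `rootSequence`, and `branchSubstitutions` (observed
#'   substitution counts per edge).
#' @examples
#' sim <- simulateDataset(simulationConfig(tree = 4L, seed = 7))
#' names(sim$genomes)
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  lay <- templateLayout(cfg$template)
  L <- lay$length
  withSeed(cfg$seed, {
    tree <- cfg$tree
    if (is.numeric(tree) && length(tree) == 1L) {
      tree <- ape::rtree(as.integer(tree))
      if (!is.null(cfg$treeDepth) && is.finite(cfg$treeDepth)) {
        depth <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
        tree$edge.length <- tree$edge.length * cfg$treeDepth / depth
      }
    }
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (is.null(tree$edge.length))
      stop("the simulation tree needs branch lengths")
    bases <- c("A", "C", "G", "T")
    pi0 <- if (cfg$model == "HKY") cfg$baseFreqs else rep(0.25, 4)
    root <- sample.int(4L, L, replace = TRUE, prob = pi0)
    nt <- length(tree$tip.label)
    seqs <- vector("list", max(tree$edge))
    seqs[[nt + 1L]] <- root
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    preLen <- tree$edge.length[match(paste(pre[, 1L], pre[, 2L]),
                                     paste(tree$edge[, 1L], tree$edge[, 2L]))]
    subs <- integer(nrow(pre))
    for (e in seq_len(nrow(pre))) {
      P <- substitutionMatrix(cfg$model, preLen[e], cfg$kappa, cfg$baseFreqs)
      parent <- seqs[[pre[e, 1L]]]
      child <- integer(L)
      for (s in 1:4) {
        at <- which(parent == s)
        if (length(at))
          child[at] <- sample.int(4L, length(at), replace = TRUE,
                                  prob = P[s, ])
      }
      seqs[[pre[e, 2L]]] <- child
      subs[e] <- sum(child != parent)
    }
    genomes <- lapply(seq_len(nt), function(i)
      annotatedGenome(tree$tip.label[i],
                      paste(bases[seqs[[i]]], collapse = ""),
                      circular = TRUE, features = lay$features))
    names(genomes) <- tree$tip.label
    list(genomes = genomes, tree = tree, loci = lay$loci,
         rootSequence = paste(bases[root], collapse = ""),
         branchSubstitutions = data.frame(parent = pre[, 1L],
                                          child = pre[, 2L],
                                          length = preLen, count = subs))
  })
}

#' Inject structural rearrangement events into a genome
#'
#' Events are applied in coordinate order and must not overlap. Palindrome
#' and duplication events overwrite the target segment (genome length is
#' unchanged); inversions reverse-complement it in place; deletions and
#' insertions change the length and must fall between feature spans
#' (feature coordinates downstream are shifted accordingly). Flanking
#' bases of palindromes and duplications are adjusted when necessary so
#' the injected event cannot extend beyond its stated coordinates, which
#' keeps the truth table exact for detector scoring.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param events data.frame with columns `kind`
#'   (`palindrome`/`duplication`/`inversion`/`deletion`/`insertion`),
#'   `start`, `length`, and for duplications `srcStart` (copy source).
#' @param seed integer seed for the random content of palindrome arms and
#'   insertions.
#' @return a list: `genome` (modified), `truth` (events with
#'   post-injection coordinates).
#' @export
injectEvents <- function(genome, events, seed = 1L) {
  if (!nrow(events)) return(list(genome = genome, truth = events))
  events <- events[order(events$start), , drop = FALSE]
  if (any(events$start[-1L] <=
          events$start[-nrow(events)] + events$length[-nrow(events)] - 1L))
    stop("injected events overlap")
  withSeed(seed, {
    s <- seqChars(as.character(genome@sequence))
    fts <- genome@features
    spans <- cbind(vapply(fts$exons, function(e) min(IRanges::start(e)), 0L),
                   vapply(fts$exons, function(e) max(IRanges::end(e)), 0L))
    shift <- 0L
    truth <- events
    truth$srcStart <- if ("srcStart" %in% names(events))
      events$srcStart else NA_integer_
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(events))) {
      st <- events$start[i] + shift
      len <- events$length[i]
      en <- st + len - 1L
      kind <- events$kind[i]
      if (kind %in% c("deletion", "insertion")) {
        inFeature <- any(spans[, 1L] <= en & spans[, 2L] >= st)
        if (kind == "deletion" && inFeature)
          stop("deletion overlaps an annotated feature")
      }
      if (kind == "palindrome") {
        if (len %% 2L != 0L) stop("palindrome length must be even")
        arm <- sample(bases, len / 2L, replace = TRUE)
        s[st:en] <- c(arm, rev(unname(comp1[arm])))
        # block extension: base before must not pair with base after
        if (st > 1L && en < length(s) && s[st - 1L] == comp1[s[en + 1L]])
          s[st - 1L] <- sample(setdiff(bases, comp1[s[en + 1L]]), 1L)
      } else if (kind == "duplication") {
        src <- truth$srcStart[i] + shift
        s[st:en] <- s[src:(src + len - 1L)]
        # block shared flanks so the repeat unit is exactly `len` long
        if (st > 1L && src > 1L && s[st - 1L] == s[src - 1L])
          s[st - 1L] <- sample(setdiff(bases, s[src - 1L]), 1L)
        if (en < length(s) && s[en + 1L] == s[src + len])
          s[en + 1L] <- sample(setdiff(bases, s[src + len]), 1L)
      } else if (kind == "inversion") {
        s[st:en] <- rev(unname(comp1[s[st:en]]))
        # block symmetric extension: the base before must not pair with
        # the base after (one substitution next to the breakpoint)
        if (st > 1L && en < length(s) && s[st - 1L] == comp1[s[en + 1L]])
          s[st - 1L] <- sample(setdiff(bases, c(comp1[s[en + 1L]],
                                                s[st - 1L])), 1L)
      } else if (kind == "deletion") {
        s <- s[-(st:en)]
        keep <- spans[, 1L] > en
        fts$exons[keep] <- lapply(fts$exons[keep], function(e)
          IRanges::shift(e, -len))
        spans[spans[, 1L] > en, ] <- spans[spans[, 1L] > en, ] - len
        shift <- shift - len
      } else if (kind == "insertion") {
        ins <- sample(bases, len, replace = TRUE)
        s <- append(s, ins, after = st - 1L)
        keep <- spans[, 1L] >= st
        fts$exons[keep] <- lapply(fts$exons[keep], function(e)
          IRanges::shift(e, len))
        spans[spans[, 1L] >= st, ] <- spans[spans[, 1L] >= st, ] + len
        shift <- shift + len
      } else stop("unknown event kind: ", kind)
    }
    # post-injection coordinates: map original positions through every
    # length-changing event (a duplication source may sit downstream of a
    # later deletion, so the per-event running shift is not enough)
    mapPos <- function(p) {
      p <- as.integer(p)
      if (is.na(p)) return(NA_integer_)
      off <- 0L
      for (i in seq_len(nrow(events))) {
        if (events$kind[i] == "deletion" &&
            events$start[i] + events$length[i] - 1L < p)
          off <- off - events$length[i]
        if (events$kind[i] == "insertion" && events$start[i] <= p)
          off <- off + events$length[i]
      }
      as.integer(p + off)
    }
    truth$start <- vapply(seq_len(nrow(events)), function(i) {
      if (events$kind[i] == "deletion")
        mapPos(events$start[i] - 1L) + 1L   # final junction position
      else mapPos(events$start[i])
    }, NA_integer_)
    truth$srcStart <- vapply(truth$srcStart, mapPos, NA_integer_)
    truth$end <- truth$start + truth$length - 1L
    g <- annotatedGenome(genome@id, paste(s, collapse = ""),
                         genome@circular, fts)
    list(genome = g, truth = truth)
  })
}

#' Simulate a mixed character matrix with planted synapomorphies
#'
#' Characters are generated by placing single derived-state changes on the
#' internal branches of a known ingroup tree (round-robin, so every
#' internal branch receives signal); with probability `homoplasyRate` a
#' character receives an extra change on a random second branch and is
#' then excluded from the planted (clean) synapomorphy list. Continuous
#' characters get a positive clade offset and are reported on the
#' standardized scale (clade state 1, background 0). A dummy outgroup row
#' coded all-primitive polarizes the changes.
#'
#' @param tree ingroup tree: `ape::phylo` or an integer number of tips
#'   (random tree under the seed).
#' @param nBinary,nUnordered,nContinuous character counts per type.
#' @param homoplasyRate per-character probability of an extra change.
#' @param seed integer seed.
#' @return a list: `matrix` (a [MixedMatrix-class] with outgroup),
#'   `tree` (the generating ingroup tree), `planted` (data.frame
#'   `branch`, `character`, `from`, `to` of clean planted synapomorphies;
#'   branch labels are the sorted comma-joined ingroup clade).
#' @export
simulateMixedDataset <- function(tree, nBinary = 12L, nUnordered = 0L,
                                 nContinuous = 0L, homoplasyRate = 0,
                                 seed = 1L) {
  withSeed(seed, {
    if (is.numeric(tree) && length(tree) == 1L)
      tree <- ape::rtree(as.integer(tree))
    nt <- length(tree$tip.label)
    if (nt < 4L) stop("the ingroup tree needs at least 4 leaves")
    desc <- descendantTips(tree)
    edge <- tree$edge
    cladeOf <- lapply(seq_len(nrow(edge)), function(e) {
      ch <- edge[e, 2L]
      sort(tree$tip.label[if (ch <= nt) ch else desc[[ch]]])
    })
    internal <- which(vapply(cladeOf, length, 0L) >= 2L &
                        vapply(cladeOf, length, 0L) <= nt - 1L)
    if (!length(internal)) stop("tree has no internal branches to mark")
    specs <- list(binary = nBinary, unordered = nUnordered,
                  continuous = nContinuous)
    parts <- list(); planted <- list()
    slot <- 0L
    for (ctype in names(specs)) {
      nc <- specs[[ctype]]
      if (!nc) next
      if (ctype == "continuous") {
        m <- matrix(0, nt, nc, dimnames = list(tree$tip.label, NULL))
      } else {
        m <- matrix("0", nt, nc, dimnames = list(tree$tip.label, NULL))
      }
      for (j in seq_len(nc)) {
        slot <- slot + 1L
        br <- internal[(slot - 1L) %% length(internal) + 1L]
        clade <- cladeOf[[br]]
        clean <- runif(1L) >= homoplasyRate
        if (ctype == "continuous") {
          delta <- runif(1L, 0.5, 2)
          m[clade, j] <- delta
          if (!clean) {
            extra <- sample(seq_len(nrow(edge)), 1L)
            m[cladeOf[[extra]], j] <- m[cladeOf[[extra]], j] + delta / 2
          }
        } else {
          m[clade, j] <- "1"
          if (!clean) {
            extra <- sample(seq_len(nrow(edge)), 1L)
            flip <- cladeOf[[extra]]
            m[flip, j] <- ifelse(m[flip, j] == "1", "0", "1")
          }
        }
        if (clean)
          planted[[length(planted) + 1L]] <- data.frame(
            branch = paste(clade, collapse = ","),
            character = sprintf("%s_%d", ctype, j),
            from = "0", to = "1")
      }
      parts[[length(parts) + 1L]] <-
        characterPartition(ctype, m, ctype = ctype)
    }
    mm <- assembleMixedMatrix(parts, dummyOutgroup = TRUE,
                              outgroupCoding = "primitive")
    list(matrix = mm, tree = tree,
         planted = if (length(planted)) do.call(rbind, planted) else
           data.frame(branch = character(), character = character(),
                      from = character(), to = character()))
  })
}
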