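---
title: "Methods behind plastophylo: marker screening, split networks and mixed-data parsimony"
author: "plastophylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind plastophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastophylo)
```

`plastophylo` targets plant groups whose chloroplast genomes are so
conserved that marker choice, not tree inference, is the limiting step.
This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Non-coding loci and variability screening

Plastid non-coding loci come in two classes. *Introns* are the gaps
between consecutive exons of a multi-exon gene feature
(`"<gene>_intron<k>"`, numbered in transcription order and
reverse-complemented for minus-strand genes). *Intergenic spacers* (IGS)
are the maximal gaps between consecutive gene-level spans along the
unfolded circle, named `"geneA-geneB"` in genomic order regardless of
strand — this matches how such markers are cited in the literature
(`trnH-psbA`, `rpl32-trnL`, ...). Features fully nested inside another
gene's span are skipped for IGS boundaries (nested tRNAs would otherwise
create zero or negative spacers), overlapping genes produce a logged
warning instead of a spacer, and for circular genomes the wrap-around
spacer is included once. Loci duplicated within one genome — the
situation for anything inside a plastid inverted repeat — are counted
once, keeping the first copy by coordinate, so identical IR copies are
not double-weighted.

Each locus alignment is scored with two statistics:

* the **normalized divergence ratio** `r = (V/C)/n`, variable over
  constant sites divided by the number of species considered. Dividing by
  `n` penalizes loci whose apparent variability merely reflects dense
  sampling; `r` is undefined (flagged, never infinite) when `C = 0`.
* the **average uncorrected p-distance** `p̄`, the mean over unordered
  sequence pairs of mismatches per pairwise-comparable site.

Site classification defaults to *complete deletion* (a column with any
gap, `N` or ambiguity anywhere is excluded) because that is the
long-standing default of the desktop programs this screening descends
from, while `p̄` uses *pairwise deletion*; both rules are arguments.
IUPAC ambiguity codes other than the four bases are always treated as
missing, never as states — a conservative choice that avoids scoring
sequencing uncertainty as divergence. The "number of species considered"
is the row count by default, with an `nSpecies` override for data sets
carrying several accessions per species.

Selection is threshold-based: a locus qualifies when `r` **and** `p̄` are
*strictly* above the thresholds, which default to the arithmetic means
over loci with defined statistics. Strict inequality is deliberate: a
locus sitting exactly at the average carries no information about being
better than average. Reference values from congeneric plastome screens
ship as `igsScreeningDefaults` (0.0023, 0.0067) and
`intronScreeningDefaults` (0.0016, 0.0042); the `"ilex2017"` pipeline
preset applies them together with the other workflow defaults
(Neighbour-Net dimension filter 4, jackknife `p = 0.36`, 1000
pseudoreplicates).

Concatenation unions the taxa, fills absent taxon-by-partition blocks
with `?`, and records 1-based inclusive column spans per partition. The
missing-data fraction counts filled cells by default; pre-existing
alignment gaps can be included via `countExistingGaps` because published
missing-data percentages are reported under both accountings and the
reader is rarely told which.

`pairwiseIdentity` uses the global-alignment convention: columns where
both rows are gaps are excluded, a gap against a residue is a mismatch,
and `N` matches nothing.

## Small structural rearrangements

Four detectors cover the event classes that distinguish congeneric
plastomes:

* **Palindromes**: maximal even-length substrings equal to their own
  reverse complement, optionally with a spacer up to `maxSpacer` between
  the arms; detection is by center expansion, and regions contained in a
  longer reported region are suppressed. Default `minLen = 20` keeps the
  expected false-positive count on a 10 kb random sequence far below one
  (a random center extends 10 steps with probability 4^-10).
* **Dispersed duplications**: exact `minLen`-mer seeds occurring more
  than once are extended to their maximal shared unit; occurrences that
  abut or overlap merge into one site, so tandem arrays count once and
  only `minCopies` (default 2) *non-tandem* sites constitute an event.
  Default `minLen = 15`.
* **Inversions**: k-mer seeds (default `k = 12`) of the query matched
  against the reverse strand of the reference chain on a common
  anti-diagonal (`i + j` constant); a chained segment is reported when it
  is at least `minLen = 20` long, verifies as an exact reverse-complement
  match, and is not forward-identical (which excludes palindromic
  segments and makes identical sequences yield nothing). Seed chaining
  rather than full local alignment is adequate for loci of a few kb and
  keeps the detector dependency-free.
* **Indels**: maximal gap runs of an alignment keyed by exact
  (start, length); rows sharing the identical run are carriers. Identical
  alignment placement, not sequence similarity, defines event homology —
  the alignment already encodes the homology statement, and merging
  near-identical offsets would conflate independent events. An event is a
  deletion when carriers are the minority and an insertion otherwise, and
  `unique` versus `shared` records whether one or several rows carry it.
  Polarization needs at least three rows.

The defaults (20/15/20) bracket the event sizes reported in comparative
plastome work (44 bp palindromes, 15 bp duplications, 44 bp inversions,
~100 bp deletions) while suppressing the noise floor of random sequence.

## Neighbour-Net and fit statistics

The Neighbour-Net stage is agglomerative: clusters (chains of taxa with
one or two active endpoint nodes) are selected with a neighbour-joining
style criterion, first between clusters using cluster-averaged distances,
then between the endpoint nodes of the selected pair; interior nodes of
the growing chain are eliminated by the 3-point reduction
`u = 2/3·x + 1/3·y`, `v = 2/3·z + 1/3·y`,
`d(u,v) = (d(x,y) + d(x,z) + d(y,z))/3`. Ties break to the smallest
index, making the ordering deterministic. Expansion of the final chain
yields a circular ordering; all `n(n-1)/2` interval splits of that
ordering are candidates, and their weights are estimated by nonnegative
least squares (Lawson-Hanson active set, via `pracma::lsqnonneg`) against
the observed distances. Because split metrics of a common circular
ordering are linearly independent, a tree metric is recovered *exactly*:
the tree's splits with weights equal to branch lengths, everything else
at zero. Splits with weight below `eps` (default 1e-6) times the mean
candidate weight are dropped.

The *dimension filter* (default 4) greedily removes the lowest-weight
split participating in a largest clique of the split incompatibility
graph until no five splits are mutually incompatible, bounding the
dimensionality of boxes a drawing would need. Relaxing the filter can
only improve `LSfit`, since the retained weights of the unfiltered
system are a superset of feasible solutions.

Fit statistics compare observed distances `d_ij` with the induced
distances `p_ij` (sum of weights of splits separating `i` and `j`):

* `fit = 100·(1 − Σ|d_ij − p_ij| / Σ d_ij)`
* `LSfit = 100·(1 − Σ(d_ij − p_ij)² / Σ d_ij²)`

summed over unordered pairs. These normalized L1/L2 residual forms are
pinned here explicitly so tests can be exact; an exact representation
gives 100 for both, an empty split system gives `fit = 0`, and all-zero
distances are flagged undefined. The equal-angle layout often drawn from
such systems is a visualization concern and not part of any contract
here; `writeSplitsNexus` exports systems (with absent trivial splits
added at weight 0) for dedicated split-graph viewers.

## Z-closure supernetworks

Input trees contribute one partial split per branch (a bipartition of
that tree's taxon set, weighted by branch length, weight 1 when lengths
are absent). The Z-closure rule extends pairs of partial splits: for
`A1|B1` and `A2|B2` with `A1∩A2 ≠ ∅`, `B1∩B2 ≠ ∅` and `A2∩B1 = ∅`, the
pair becomes `(A1∪A2)|B1` and `A2|(B1∪B2)`, applied only when a side
strictly grows. This is the orientation of the rule that is *sound*:
whenever the two partial splits are restrictions of one full split, both
replacements are again restrictions of it, which is what lets congruent
partial trees merge into their common supertree splits. Applied to
genuinely conflicting splits it completes both signals, and the completed
full splits then intersect pairwise — the incompatibility boxes that make
supernetworks useful. Note that a taxon private to one tree can only
enter another tree's splits accompanied by context from its own tree;
when a private taxon hangs off a basal polytomy of a conflicting tree,
the conflicting splits may simply never complete. That is a property of
the closure, not a bug, and the test fixtures therefore nest private
taxa inside clades.

Because the in-place rule application is order-dependent, the closure is
repeated over `orderings` random pair orders (seeded) and completed full
splits are pooled; a completed split's weight is the mean length of the
input branches that produced it. Taxa whose trivial split never completes
receive it with their mean pendant length, so every taxon appears in the
output. The pooled split set stabilizes quickly on small instances but
should be treated as a heuristic summary on sparse taxon overlap; the
package reports whatever completed, and reproducibility is guaranteed by
the seed, not by convergence. Sides are manipulated as bit masks up to 30
taxa (the practical range for this kind of analysis), with a plain-set
fallback above that.

## Total-evidence parsimony

`MixedMatrix` objects carry typed partitions: DNA (optionally with the
gap as a fifth state — the usual coding when indels in non-coding loci
are believed informative), binary (AFLP presence/absence), unordered
multistate (morphology; treated non-additive unless the user codes
otherwise, which is the common default for such data), and continuous.
Continuous characters are range-standardized at assembly:
`x → (x − min)/(max − min)`, so a change between the two most dissimilar
observed states costs exactly one step and quantitative characters are
commensurate with discrete ones; zero-range characters are excluded with
a warning. A dummy outgroup row polarizes character change and is coded
all-`?` by default (it then adds no steps anywhere) with an all-primitive
option — and the simulator uses the primitive coding, because with an
all-`?` outgroup the *direction* of a change on the tree's central
branches is genuinely ambiguous.

Scoring: discrete characters use uniform-cost dynamic programming over
states (the Fitch count on binary trees, exact on multifurcations too);
continuous characters use Farris interval (L1) optimization, implemented
as V-shaped envelopes (interval bottom plus unit-slope arms) that are
closed under the combine-and-smooth recursion, making the optimization
exact on arbitrary trees — sums of such envelopes have integer slopes, so
the 1-Lipschitz envelope of a node's aggregated cost is again V-shaped.
Missing entries force no steps.

The exact search is branch and bound: taxa are added in max–min distance
order (ties to the smallest index), the score of a partial tree is a
valid lower bound for any completion, and a greedy-addition tree seeds
the upper bound. All most-parsimonious trees are retained (pruning only
strictly worse partials), deduplicated by split set. The search refuses
more than 14 taxa: the tool targets the small taxon sets of
total-evidence studies, and heuristic search is deliberately out of
scope. Inside the search, leaves are pre-encoded (discrete states as bit
masks) so each candidate tree is scored with a handful of vectorized
operations.

`CI = Σmin/score` and `RI = (Σmax − score)/(Σmax − Σmin)` use
per-character bounds: a discrete character needs at least
(observed states − 1) steps and at most (observations − largest state
class) steps, the star-tree value; a continuous character needs at least
its standardized range (1 by construction when fully observed) and at
most the star-tree value `Σ|x_i − median|`, the natural continuous
analogue — resolving a star can only shorten an L1 reconstruction, so it
is a true upper bound. A matrix of only uninformative characters makes
every topology tie at score 0; the result is flagged and `CI` is `NA`.

Support comes from resampling characters as columns — continuous
characters as single units like any other column, the simplest consistent
treatment: the bootstrap draws columns with replacement, the jackknife
deletes each column independently with probability `p` (0.36, the
classical e^{-1} deletion fraction). A clade's support is the percentage
of replicates whose strict consensus of most-parsimonious trees contains
it. With a single informative character the clade survives exactly when
the character does, so jackknife support calibrates to `1 − p` — a test
anchors this at 64% ± binomial noise.

Synapomorphy mapping roots the tree at the dummy outgroup and reports
changes present on the same branch with the same direction in *every*
most-parsimonious reconstruction. For discrete characters all optimal
reconstructions are enumerated from the dynamic programme (a state is
admissible given the parent's state exactly when it attains the subtree's
optimal contribution) and their change sets intersected; the enumeration
aborts early once the intersection empties, and characters exceeding
`enumLimit` reconstructions are conservatively reported as ambiguous.
For continuous characters a change on a branch is *forced* when the
optimal-value intervals of the two half-trees separated by the branch are
disjoint; the direction is then determined and the interval gap is the
minimal forced magnitude, which is what gets reported (larger changes may
occur in particular reconstructions, the gap is what every reconstruction
must contain).

## The synthetic data generator

`simulateDataset` evolves a template plastome along a tree under JC, K2P
or HKY (closed-form transition matrices for JC, eigendecomposition
otherwise, scaled to one expected substitution per site per unit branch
length), site-independently and without spontaneous indels — structural
events enter only through `injectEvents`, which keeps every truth table
exact. The default template is a desk-scale proxy: 12 genes with real
plastid gene names, two of them multi-exon so intron loci exist, on a
20 kb circle; the ground-truth locus table is derived from the template
by direct cumulative arithmetic, independent of the extraction module it
oracles. When the tree is drawn randomly, branch lengths are rescaled so
the mean root-to-tip path is `treeDepth = 0.005` substitutions per site,
the divergence regime of congeneric plastomes (pairwise identity near
99%).

`injectEvents` applies palindromes, duplications, inversions (in-place),
deletions and insertions (length-changing, restricted to intergenic
space) in coordinate order, refusing overlaps, and reports post-injection
coordinates — including duplication sources shifted by later deletions.
Where a flanking base would let a detector extend an event beyond its
injected extent by chance (one-in-four per flank), the generator
substitutes that single base; this is what makes "recovered with exact
coordinates" a meaningful, deterministic assertion.

`simulateMixedDataset` plants single derived-state changes round-robin on
the internal branches of a known ingroup tree (so every branch carries
signal and the generating tree is the unique MP tree when homoplasy-free),
with an optional per-character homoplasy rate that adds a second change
and removes the character from the planted (clean) synapomorphy list.

What the generator does **not** emulate: quadripartite LSC/SSC/IR
architecture (so IR-duplicated loci only arise in hand-built fixtures),
rate heterogeneity across sites, alignment error (simulated loci are
gap-free and need no aligner), and coalescent gene-tree discordance.
Passing tests therefore certify the algorithms against their own
definitions and against exact ground truth — not robustness to
misalignment or model misspecification on real data.

## Problem sizes and determinism

Test-suite and acceptance runs use desk-scale sizes chosen to exercise
every code path with exact oracles: 20 kb genomes, trees of 5–12 taxa for
network recovery (100 replicates), 6-taxon matrices for exhaustive
parsimony enumeration (all 105 unrooted trees, 20 replicates), 7–9 leaf
matrices for planted-synapomorphy recovery, and 1000 jackknife
pseudoreplicates for the calibration check. All stochastic steps take
explicit seeds; generators restore the caller's RNG state, and the
pipeline manifest records md5 checksums so deterministic stages reproduce
bit-identically.

## Known limitations

* Exact search only (≤ 14 taxa); no heuristic tree search, no implied
  weighting, no likelihood or Bayesian inference — likelihood trees are
  consumed as newick inputs, never inferred.
* IGS handling across inverted-repeat boundaries follows the
  first-copy-by-coordinate convention; other conventions exist.
* The Z-closure pool is a seeded heuristic; on sparsely overlapping
  inputs different orderings can complete different split subsets.
* Continuous characters resample as whole columns in bootstrap and
  jackknife; treating them as divisible information is not supported.
* Trans-spliced genes are parsed but never used as marker loci.
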