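---
title: "Dissecting quartet signal in phylogenomic supermatrices"
author: "quartetSignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting quartet signal in phylogenomic supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetSignal)
library(ape)
```

## The problem

When four predefined clades — say the four myriapod subgroups Chilopoda,
Diplopoda, Pauropoda and Symphyla — have contested relationships, the
space of hypotheses factorises neatly. Any four groups admit exactly
**three unrooted quartet topologies** (the three ways of pairing them
into two cherries), and each topology admits **five rooted derivatives**
(one per edge that can carry the root), fifteen rooted trees in all.
Competing published phylogenies often differ only in the placement of
the root on a single underlying quartet topology — a disagreement about
character polarisation — whereas trees drawn from different topologies
are genuinely incongruent. Separating these two kinds of conflict, and
asking whether apparent support for a topology survives controls for
non-phylogenetic signal, is what this package automates.

Three instruments are combined:

1. **Four-cluster Likelihood-Mapping (FcLM).** Draw quartets with one
   taxon per cluster, compute the maximum-likelihood support for each of
   the three topologies, and map the normalised weights onto the
   2-simplex.
2. **The approximately unbiased (AU) test** over a set of candidate
   trees, via multiscale RELL bootstrap of site log-likelihoods.
3. **Matched-pairs symmetry diagnostics (Bowker's test)** and
   **signal-destroying permutations**, which respectively detect and
   isolate confounding signal: among-lineage compositional heterogeneity
   (violations of stationarity, reversibility and homogeneity — SRH)
   and non-randomly distributed missing data.

## Supermatrix compilation

`concatenateMatrices()` unions per-gene alignments into a partitioned
supermatrix; absent taxon-gene blocks become missing blocks. Two
coverage filters mirror standard compilation rules:

* `filterStrict()` keeps partitions in which *every* taxon is
  represented — the 100%-coverage rule;
* `filterRelaxed()` keeps partitions represented by at least one member
  of each required group.

"Represented" means at least one non-missing residue in the partition;
the threshold is presence/absence, not a length fraction, which is the
convention of the transcriptome-pipeline matrices this mirrors. For
nucleotide matrices, `selectCodonPositions()` retains chosen codon
positions (typically the second, the least SRH-violating), with the
reading frame restarting at each partition boundary.

`completeness()` reports AliStat-style scores: the overall percentage of
non-missing cells (Ca), per-taxon scores (Cr), and the taxon-pairwise
shared-coverage matrix. The diagonal of the pairwise matrix is fixed at
1 by convention. Partition ranges are held 1-based inclusive throughout,
matching the RAxML partition-file convention used by `readPartitions()`
and `writePartitions()`.

## Symmetry diagnostics

For two aligned sequences, `pairCounts()` tabulates residue pairs over
sites covered in both (pairwise deletion), and `bowkerTest()` computes

$$B = \sum_{u<v} \frac{(n_{uv} - n_{vu})^2}{n_{uv} + n_{vu}},$$

chi-square distributed with one degree of freedom per informative
unordered pair under the null of a symmetric joint distribution — which
holds for any stationary, reversible, homogeneous process. `srhScan()`
applies the test to all pairs and reports the percentage rejecting at a
chosen level, without multiple-testing correction (the convention in
which such heatmap summaries are quoted).

Two power caveats matter in practice, and shape our tests. First, with
amino-acid data the 20×20 pair table is sparse unless alignments are
long, making the chi-square approximation conservative; calibration
checks therefore use nucleotide simulations, where the 4×4 tables are
well filled. Second, rejection fractions across the pairs of one
alignment are strongly correlated (pairs share taxa), so the ≈5%
calibration property is checked on *independent* two-taxon simulations,
where binomial tolerance is meaningful.

## The likelihood engine

`siteLogLik()` implements Felsenstein pruning for reversible models
(Poisson/custom empirical matrices for amino acids; JC/GTR for
nucleotides), with empirical equilibrium frequencies by default,
discrete-gamma rate heterogeneity (equal-probability categories, mean
rate 1), missing residues marginalised as all-ones tip partials, and
per-pattern scaling against underflow. Identical site patterns are
collapsed with weights. Transition matrices come from the eigendecomposition
of the symmetrised rate matrix, rescaled to one expected substitution
per unit branch length.

`optimizeBranchLengths()` performs coordinate-wise Brent search per
branch with conditional likelihoods cached on both sides of the branch
(the per-branch objective reduces to a one-dimensional function through
the eigenbasis), cycling until the log-likelihood improves by less than
1e-6, with a 100-cycle cap. Branch lengths are bounded in [0, 10] and
start at 0.1. Hitting the cycle cap raises a warning and returns the
last iterate rather than failing; this occurs on likelihood surfaces
that are nearly flat, e.g. permuted (signal-free) alignments. The
engine reproduces an independent implementation's optimised
log-likelihoods to numerical identity on shared test cases, and pruning
is verified against exhaustive summation over internal-node states.

FcLM and AU computations default to a single model for the whole matrix
(Poisson+Γ4 with empirical frequencies for amino acids, GTR+Γ4 for
nucleotides). Per-partition model maps are deliberately out of scope:
partitioned model selection is an upstream concern, and the quartet
diagnostics the package exists for are robust summaries, not final
inference.

## FcLM and the seven-region simplex

For each drawn quartet (exhaustive up to a cap, seeded subsampling
beyond it), the three topologies are each fitted by ML and the weights
$p_i = \exp(\ell_i - \ell_{\max}) / \sum_j \exp(\ell_j - \ell_{\max})$
place the quartet in the simplex. Classification into seven regions is a
nearest-generator (Voronoi) rule in barycentric coordinates: the three
corners (resolved topologies), the three edge midpoints (pairwise
ambiguity) and the centroid (star-like signal), with ties broken toward
the lowest cell index. With clusters drawn in order (c1, c2, c3, c4),
the corner convention is T1 = (c1,c2)|(c3,c4) → cell 1,
T2 = (c1,c3)|(c2,c4) → cell 2, T3 = (c1,c4)|(c2,c3) → cell 3; the edge
cells are 4 (T1–T2), 5 (T2–T3), 6 (T1–T3), and the centre is cell 7.
The exact interior boundaries used by other implementations are not
published; the Voronoi construction is this package's explicit,
documented commitment.

```{r simplex, eval = FALSE}
gm <- setNames(rep(c("A", "B", "C", "D"), each = 3),
               paste0(rep(c("a", "b", "c", "d"), each = 3), 1:3))
rep <- fclmReport(x, gm, c("A", "B", "C", "D"), seed = 1)
cellPercentages(rep)
```

## Permutation controls

Three schemes destroy different components of signal while always
leaving the missing-data mask untouched (so non-random data distribution
remains embodied in every permuted matrix):

* **Scheme I** shuffles each taxon's non-missing residues across its
  non-missing positions matrix-wide — destroying site-wise phylogenetic
  signal while preserving lineage composition;
* **Scheme II** does the same independently within each partition —
  additionally preserving per-partition composition;
* **Scheme III** shuffles within columns among covered taxa —
  destroying lineage identity while preserving per-site composition.

The schemes' published descriptions are not printed in full anywhere we
could verify; these definitions are committed to by their purpose —
isolating (a) among-lineage heterogeneity and (b) non-random data
distribution — and the registry is pluggable. Seeding derives one
deterministic stream per taxon (I, II) or per column (III) from the
master seed. `fclmWithPermutations()` assembles the original-plus-
permutations table and flags a corner topology as "explainable by
confounding signal" when its original support does not exceed its
maximum permuted support by more than a stated margin (default 5
percentage points).

A subtlety worth recording: after a scheme-I shuffle, taxa are
independent given their compositions, so a quartet in which only *one*
pair of lineages shares a shifted composition carries no topological
information (any topology fits one short pair). Confounded corner
support that survives scheme I — the fingerprint of compositional
attraction — requires at least two lineage pairs with distinct
compositions, and that is how the package's confounding tests are
constructed.

## AU test

`auTest()` takes a trees × sites log-likelihood matrix (from
`siteLogLikMatrix()` or an external program via `readSlm()`). Bootstrap
proportions BP(r) are computed at scales r ∈ {0.5, …, 1.4} (10,000
replicates each by default) by RELL resampling — per-site
log-likelihoods are resampled, never re-optimised. Each tree's
z(r) = Φ⁻¹(1 − BP(r)) is fitted by weighted least squares to
z(r) = d·√r + c/√r with binomial delta-method weights, BP values clipped
to [1/(2B), 1 − 1/(2B)]; then p_AU = 1 − Φ(d − c). Trees with
numerically indistinguishable score rows — rooted variants of one
unrooted topology, whose independently optimised rows agree to within
the branch-length convergence tolerance — are collapsed into score
classes that share a p-value, with the mapping reported. Degenerate
classes (BP 0 or 1 at every scale) get p = 0 or 1 with a flag.

## The synthetic generator

`simulateAlignment()` evolves sites independently down a guide tree:
root states from the model frequencies, branch transitions via the
matrix exponential, per-site discrete-gamma rate multipliers, and two
missingness mechanisms that mimic transcriptome supermatrices — whole
taxon × gene dropout blocks plus per-cell noise. Non-stationarity is
generated by frequency switching at designated branches with
exchangeabilities held fixed, the simplest mechanism that produces
Bowker-detectable asymmetry.

`myriapodFixture()` instantiates the sampling design the package's
end-to-end checks run against: 59 amino-acid taxa (16 centipedes, 10 millipedes, 1
pauropod, 3 symphylans, 20 pancrustaceans, 7 chelicerates, 2
onychophorans) on a tree pairing Chilopoda+Diplopoda and
Pauropoda+Symphyla over a mandibulate backbone, ten gene partitions,
gamma rate heterogeneity (shape 0.8), composition shifts placed so that
heterogeneity crosses the true split (one pauropod, one centipede, one
pancrustacean share a shifted composition), 15% gene dropout and 2%
cell noise. With these group sizes, one-per-group quartet drawing gives
exactly 480 quartets.

What the generator does *not* emulate: indels and alignment error,
codon structure, site-specific profiles (CAT-like heterogeneity),
per-gene model variation, and realistic gene-tree discordance. Passing
tests on these simulations therefore demonstrate correctness of the
machinery and qualitative behaviour of the diagnostics, not performance
guarantees on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen as the smallest that exercise each property cleanly: FcLM
signal-recovery uses 4 clusters × 3 taxa (81 quartets) on 2,000
amino-acid sites with terminal depth 0.2 and internal branch 0.3;
branch-length recovery uses one quartet at 10,000 nucleotide sites;
Bowker calibration uses 300 independent two-taxon alignments of 2,000
sites; the AU pattern check uses 4,000 sites and all fifteen rooted
candidates; the 59-taxon fixture is analysed with a seeded 60-quartet
subsample. Key numerical commitments: branch bounds [0, 10], start 0.1,
log-likelihood tolerance 1e-6 (cycle cap 100, warning on hitting it);
BP clipping 1/(2B); score-class tolerance 1e-3 on per-site
log-likelihood differences; Voronoi ties toward the lowest cell index;
ambiguity codes beyond X/N (B, Z, J; IUPAC) treated as missing.

## Limitations

* Bowker's test on amino-acid matrices below ~10⁴ sites is conservative
  (sparse tables); nucleotide data or long matrices are needed for
  calibrated rejection rates.
* FcLM weights inherit every limitation of the single substitution
  model; confounding diagnosis by permutation is qualitative, not a
  formal test.
* The AU implementation uses RELL, not per-replicate re-optimisation;
  this is standard but approximate for short alignments.
* The CLI and file formats cover the analysis path end to end but only
  plain-text formats (FASTA, RAxML partitions, TSV, JSON, Newick).
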