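---
title: "Genome-based taxonomy with GBDP distances and digital DDH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based taxonomy with GBDP distances and digital DDH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdtax)
```

## The problem

The classical criterion for deciding whether two bacterial strains belong to
the same species is 70% DNA:DNA hybridization (DDH) similarity. Wet-lab DDH
is noisy and non-reproducible, so modern taxonomy replaces it with *digital
DDH* (dDDH): an intergenomic distance is computed from whole-genome
assemblies and transformed through a calibrated model so that, on average,
it mimics the wet-lab scale. The same machinery extends below the species
level: a boundary in the 79--80% dDDH range delineates subspecies, and the
question of *where exactly* to put that boundary can be answered with a
clustering-stability argument rather than taste.

`gbdtax` implements this workflow end to end for desk-scale genome sets:

1. local matching of genome pairs into high-scoring segment pairs (HSPs),
2. overlap resolution by greedy-with-trimming,
3. GBDP distance formulas over the trimmed HSP set,
4. logistic conversion of distances to dDDH,
5. type-strain-anchored species/subspecies assignment with an advisory
   G+C-content check,
6. OPTSIL-style threshold clustering, cluster statistics, partition
   agreement, and the clustering-consistency criterion,
7. distance trees with pseudo-bootstrap support,
8. a sequence-evolution simulator that plants a species/subspecies
   hierarchy so every stage can be validated against known truth.

## Intergenomic distances (GBDP)

For a genome pair, the matcher finds ungapped local alignments: exact
$k$-mer seeds ($k = 11$) on both strands, deduplicated per diagonal, then
extended with an X-drop rule (match $+1$, mismatch $-2$, drop 20).
Matches shorter than 100 bp or below 70% identity are discarded. Replicons
of one assembly are concatenated with a $2k$-base spacer of `N`s, which can
neither seed nor be crossed by an extension, so matches never bridge
replicon joins.

Raw HSPs overlap. **Greedy-with-trimming** resolves this: HSPs are visited
in decreasing score order (ties: longer first, then smaller coordinates);
every sub-span of a later HSP that overlaps the accepted footprint on
*either* genome is removed. Because HSPs are ungapped, trimming is exact
coordinate slicing, and each HSP carries its mismatch offsets so identities
are recounted exactly on any slice. Slices shorter than the minimum length
are dropped. The accepted set is footprint-disjoint on both genomes.

With $H$ the summed HSP lengths, $I$ the summed identities, and
$L = |A| + |B|$, three distances are defined:

$$d_{\mathrm{cov}} = 1 - \frac{2H}{L}, \qquad
  d_{2} = 1 - \frac{I}{H}, \qquad
  d_{\mathrm{tot}} = 1 - \frac{2I}{L}.$$

Formula 2 (identities per HSP length) is the default: it is insensitive to
incomplete assemblies and is the formula behind the published dDDH
thresholds the package defaults to. $d_2$ is defined as 1 when $H = 0$ (no
evidence of homology), with a warning.

A deliberate fidelity note: the reference implementations of GBDP run NCBI
BLAST. `gbdtax` ships its own deterministic seeded matcher instead, so the
tool has no external binary dependency and results are bit-reproducible;
gapped extension is omitted, which keeps trimming exact. Tabular BLAST
output (`outfmt 6`) can be imported with `read_blast_tab()` for fidelity
runs against the original matcher.

## From distance to dDDH

The conversion is a strictly decreasing logistic
$$y(d) = \frac{1}{1 + e^{c_0 + c_1 d}}, \qquad c_1 > 0,$$
mirroring the generalized-linear-model calibration of the
Genome-to-Genome Distance Calculator (GGDC). The GGDC's fitted
coefficients for formula 2 are not re-estimated here; instead the default
model is pinned through two published anchor points of that calibration:
the canonical species boundary ($d = 0.0359 \leftrightarrow 70\%$ dDDH) and
the subspecies-range anchor ($d = 0.0242 \leftrightarrow 79.3\%$ dDDH).
Two points determine $(c_0, c_1)$ exactly; the constructor recomputes the
second anchor and refuses to build a model that misses it by more than
0.5 dDDH points. That the two anchors are collinear on a single logistic
(slope $\approx 42.4$) is itself a useful consistency check of the
calibration.

```{r}
m <- ddh_model()
m
distance_to_ddh(c(0.0242, 0.0359), m)
```

`classify_vs_type()` applies the thresholds relative to a designated type
strain: dDDH $\ge$ 70% means same species, dDDH $\ge$ 79% (configurable
within the 79--80% band) means same subspecies, with $\ge$ used at the
boundary. A strain inside the species whose G+C content differs from the
type strain by more than 1 percentage point is flagged — within-species
G+C differences above 1 point are empirically rare, so the flag marks
suspicious assignments — but the flag never overrides the dDDH call,
because G+C content has no resolution between closely related species.

G+C content is computed as $(G + C)/(A + C + G + T)$ with ambiguous IUPAC
symbols excluded from numerator and denominator, so unknown bases do not
bias the composition; all statistics pool the whole assembly (chromosome
plus plasmids).

## Threshold clustering and the subspecies boundary

`threshold_cluster(m, T, F)` is an agglomerative scheme controlled by a
distance threshold $T$ and a linkage fraction $F$: starting from
singletons, the cluster pair with the smallest average inter-cluster
distance among those passing the linkage test is merged until no pair
qualifies. The linkage test requires at least one inter-cluster pair with
$d \le T$ and a fraction $\ge F$ of such pairs. $F = 0$ is single linkage
(provably the connected components of the graph $\{d \le T\}$, which the
tests verify against an independent graph traversal), $F = 1$ is complete
linkage, intermediate values interpolate. Merge order and tie-breaking
(smallest average distance, then lexicographically smallest member label)
are fully specified so partitions are reproducible.

On perfectly *ultrametric* data every within-cluster distance is smaller
than every between-cluster distance, and all linkages produce the same
partition at every threshold. Real genome distances are not ultrametric,
and the disagreement between linkages is exactly the source of
threshold-clustering paradoxes. **Clustering consistency** turns this into
a criterion: for a threshold $T$, partition each within-species distance
matrix at $(T, F{=}0)$ and $(T, F{=}1)$ and score their agreement
(adjusted Rand index; identical partitions score 1, including the
degenerate all-singleton and single-cluster cases where the index is
undefined). The criterion is isolated behind one function so an
alternative formula could be swapped in.

`optimize_subspecies_threshold()` scans a threshold grid — by default the
midpoints between consecutive observed distances, i.e. one representative
per step of the (piecewise-constant) consistency profile — and returns the
midpoint of the widest maximal-consistency plateau. Because each grid
point stands for the whole interval between its two neighboring observed
distances, plateau width is measured after extending each run of maximal
grid points halfway toward its off-plateau neighbors; a plateau touching
the end of the grid is flagged `degenerate_plateau` (no substructure above
the covered range), and an all-non-positive profile returns a
`no_consistent_threshold` status rather than an error. On data with a
clean band structure the selected threshold is the centre of the gap
between the within-subspecies and between-subspecies distance bands.

Agreement between partitions is the adjusted Rand index computed from the
contingency table. The original OPTSIL program reports a modified Rand
variant; the adjusted index was chosen as the standard
chance-corrected statistic, and the tests pin it to a brute-force
pair-counting oracle and to an independent library implementation.
`optimize_against_reference()` grid-searches $(T, F)$ for maximal
agreement with a reference partition (e.g. phylotypes), resolving ties
toward smaller $T$ then smaller $F$; its default grid adds one point below
the smallest observed distance so the all-singleton partition is
attainable.

`cluster_stats()` reports per-cluster size, average and maximum
within-cluster distance, and min/median/max summaries across clusters with
at least two members (singletons carry no within-cluster information). The
median is deterministically the lower of the two middle values for even
counts.

## Trees and pseudo-bootstrap support

Tree inference stands on `ape`: neighbor joining by default (exact on
additive matrices), or balanced minimum evolution with
nearest-neighbor-interchange (`method = "bme"`, via `ape::fastme.bal`) —
a deterministic, desk-scale substitute for a full FastME search. Negative
NJ branch lengths are clamped to zero. Rooting requires the outgroup to
form one side of a bipartition of the unrooted tree and errors otherwise;
`is_monophyletic()` tests whether a label set is exactly the descendant
set of one node.

Branch support uses the *pseudo-bootstrap*: instead of resampling
alignment columns (there is no global alignment), each genome pair's
trimmed HSPs are resampled with replacement ($n$ out of $n$) and the
distance recomputed; each replicate matrix is re-built into a tree with
the same settings as the point estimate, and a branch's support is the
percentage of replicate trees containing the same bipartition. Each
(replicate, pair) draw gets its own RNG stream derived from
(seed, replicate, pair), so replicate matrices are reproducible and
independent of pair evaluation order. A pair resolved by a single HSP has
zero replicate variance by construction, and a pair with no HSPs is fixed
at distance 1. All support values are kept in the data layer; the
customary "show if larger than 50%" rule is applied only when rendering
(`write_tree_newick(..., hide_support_below = 50)`).

## The simulator: what it emulates and what it does not

`simulate_taxon_set()` evolves a random ancestor (default 50 kb, G+C 0.50)
independently along a fixed hierarchy tree — by default 3 species × 2
subspecies × 4 strains — with per-branch substitutions (uniform over the
three alternative bases, Jukes–Cantor-like; the workflow estimates
identity fractions, not model-based distances), point indels (rate
$10^{-4}$ per base per branch, geometric lengths with mean 3), and segment
inversions (0.1 expected per branch, mean length 1 kb). Indels fragment
the single ancestral alignment into many HSPs, which is what gives the
pseudo-bootstrap something to resample; inversions exercise the
reverse-strand path of the matcher. At G+C 0.50 the substitution model is
composition-neutral in expectation, which is what makes the within-species
1-point G+C rule hold on synthetic cohorts.

Per-branch substitution probabilities are calibrated at run time from the
configured dDDH model (never hard-coded): the between-subspecies band is
centred at dDDH 0.75 (the centre of the 72--78% range), the
within-subspecies band is placed mirror-symmetric *in distance* about the
intended subspecies boundary at dDDH 0.79 — forced by the plateau-midpoint
rule, which selects the centre of the gap between the two bands — and the
between-species band is centred at dDDH 0.40, comfortably below the 70%
species line. Pairwise divergence targets are converted to per-branch
probabilities through the closed form $D = 2s - \tfrac{4}{3}s^2$ for two
lineages with cumulative substitution probability $s$, and cumulative
probabilities are decomposed multiplicatively across levels. Truth records
carry the hierarchy tree, one partition per level, and exact expected
pairwise divergences computed from the transition-matrix algebra of the
uniform model.

What the simulator does *not* emulate: horizontal transfer and
recombination, repeat families, compositional heterogeneity along the
genome, assembly artifacts (contig fragmentation, contamination), and
rate variation across lineages. Passing tests on synthetic cohorts
therefore demonstrate the correctness of the distance/clustering/tree
machinery under clean vertical descent, not robustness to the full
messiness of real assemblies.

## Numerical choices and problem sizes

* Tolerances: the dDDH anchor is enforced to ±0.5 points; inverse
  transforms round-trip to $10^{-9}$; merge-tie comparisons use an
  absolute guard of $10^{-15}$ on average distances.
* Degenerate inputs: empty HSP sets give distance 1 (warning under
  formula 2); pairs with no HSPs get bootstrap distance 1; all-singleton
  and single-cluster partitions score consistency 1 when identical;
  sequences with no unambiguous bases raise an undefined-composition
  error.
* Determinism: one top-level seed derives every stage stream by stable
  hashing of (seed, stage, context); matcher tie-breaks are total, so
  whole pipeline runs are byte-identical under a fixed seed.
* Problem sizes: the validation suite runs 50-kb genomes for the full
  3×2×4 cohort (276 genome pairs) and 15--20-kb genomes for smaller
  fixtures; these sizes give per-pair standard errors on the mismatch
  fraction of about $6 \times 10^{-4}$, an order of magnitude smaller than
  the band gaps being resolved, while keeping a full run in tens of
  seconds on one CPU.

## Known limitations

* Ungapped HSPs only; heavily indel-rich pairs lose more aligned length
  than gapped GBDP would, slightly inflating coverage-based distances.
* The default dDDH calibration applies to formula 2; models for the other
  formulas must be supplied explicitly.
* The clustering-consistency operationalization (single- vs
  complete-linkage agreement) is one member of the family of stability
  criteria; it is deliberately isolated in `clustering_consistency()`.
* OPTSIL's silhouette mode and fuzzy clusters are out of scope, as are
  likelihood/parsimony phylogenies and gene-content analyses.
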