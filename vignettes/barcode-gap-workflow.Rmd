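---
title: "Methods: distances, the barcode gap, identification and MOTU delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distances, the barcode gap, identification and MOTU delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

`barcodegap` implements the complete analysis chain of a DNA-barcoding
campaign over a regional reference library of aligned COI sequences:
pairwise divergences, barcode-gap profiling, leave-one-out identification
simulation, species delimitation into molecular operational taxonomic
units (MOTUs), species/MOTU concordance, gene trees with bootstrap
support and per-species tests of isolation by distance. This vignette is
the package's account of the methods themselves — the models, the
parameters that matter, the numerical choices, and what the bundled
synthetic-data generator does and does not emulate.

## Distances

All downstream stages consume one symmetric pairwise distance matrix.
Two models are provided, both under *pairwise deletion*: for each pair of
sequences, only positions where both carry an unambiguous A/C/G/T are
compared; gaps and every IUPAC ambiguity code are excluded outright
rather than fractionally matched, which is the convention of the
distance tools this field uses.

* **p-distance**: the proportion of differing comparable sites,
  `P + Q`, where `P` and `Q` are the transition (A↔G, C↔T) and
  transversion fractions.
* **Kimura 2-parameter (K2P)**: `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`,
  the standard model of barcoding studies. K2P ≥ p always, with equality
  only at zero divergence.

When a log argument is non-positive (saturation) or a pair shares no
comparable sites, the distance is *inestimable*: it is stored as `NA`
with a warning and excluded from summaries, never silently zeroed.
Tree building refuses matrices with inestimable pairs outright.
Distances are fractions internally; reports print percentages.

## The barcode gap

For every sequence the profile records the distance to its *furthest
conspecific* (absent for singletons) and to its *nearest non-conspecific*
(the nearest neighbour, NN). A species with two or more members shows a
barcode gap when every member's NN distance strictly exceeds that
member's furthest-conspecific distance. Barcode *sharing* means distance
zero under pairwise deletion — identical over all mutually comparable
sites — not string equality, so a sequence with a few ambiguity calls can
still share its barcode.

Two empirical thresholds summarise the pools: the 95th percentile of all
intraspecific distances and the 5th percentile of all congeneric
distances. The percentile rule is fixed package-wide as linear
interpolation between closest ranks (`stats::quantile` type 7); the
upstream tools never state theirs, so one compliant rule is declared
once and used everywhere.

Singletons cannot be assessed through intraspecific variation, so they
are assessed on the gene tree: a singleton is *distinguishable* when its
barcode is unshared and its tip is not nested inside the smallest clade
containing its nearest non-conspecific species. The tree is midpoint
rooted before clade queries, a choice that only affects the degenerate
case where the nesting clade spans the root.

## Identification simulation

Each member of a species with at least two sequences is queried against
the rest of the library (itself removed; singletons remain as potential
matches; unlabeled records neither query nor match, as they can neither
be scored nor confer a name). Three criteria are scored:

* **BM** (best match): the closest match names the query, regardless of
  divergence.
* **BCM** (best close match): as BM, but only matches within a distance
  threshold count; no match inside means *no identification*.
* **BIC** (BOLD-style criterion): *every* candidate within the threshold
  must belong to one species; several species make the query
  *ambiguous*, one foreign species makes it *incorrect*.

Ties at the decisive distance spanning two or more species are
ambiguous; ties among conspecifics only are correct. "Within the
threshold" is inclusive (`<= t`), the BOLD-style convention, fixed and
documented here. Outcome categories always sum to the number of queries.

Four threshold-selection rules feed the BCM/BIC panel:

1. the 95th percentile of intraspecific distances;
2. the fixed 1% convention of the BOLD identification engine;
3. the **cumulative-error optimum**: the threshold minimising false
   negatives (queries whose nearest conspecific lies beyond `t`) plus
   false positives (queries with a non-conspecific within `t`). The
   error curve is piecewise constant between observed distances, so the
   default grid is every observed distinct value plus midpoints, and the
   panel uses the midpoint of the minimising band;
4. the **density minimum**: a Gaussian kernel density over all pairwise
   distances (bandwidth `bw.nrd0`, 512 grid points over `[0, max]`); the
   threshold is the *first* interior local minimum, the dip where the
   density leaves the intraspecific peak. The deepest minimum is
   deliberately not used: in libraries whose large divergences thin out
   into a sparse tail, kernel wiggles there produce arbitrarily low
   minima that have nothing to do with the intra/interspecific
   transition. A unimodal density yields an explicit "no minimum"
   signal and the panel falls back to a configured default (or drops the
   column with a warning).

## MOTU delimitation

Three clusterers, all returning total, disjoint partitions:

**Barcode-gap discovery (ABGD-style).** All pairwise distances are
sorted; the partition links every pair below the first significant gap
above a prior intraspecific divergence `P`, components being the MOTUs.
The published description leaves detection details open; this package
fixes them as follows, all exposed as arguments and recorded in the
partition's parameters. Detection runs on the sorted *unique* distance
values (tie handling); the local slope at a candidate gap is the mean of
up to 10 preceding unique-value gaps; a gap is significant when wider
than `X` times that slope (`X` = 1.5 by default, to capture only large
gaps); a candidate with no preceding gaps carries no slope information
and must instead be at least `min_gap` wide (default `P`). The recursive
variant re-applies detection inside each group using that group's own
sub-distribution — gaps masked globally by other taxa's distances become
visible there — and never re-splits groups of fewer than three
sequences. Raising `P` can only coarsen the initial partition, and
recursive counts are never below initial ones.

**Statistical-parsimony clustering (TCS-style).** Sequences are linked
when they differ at no more than `J` comparable sites, where `J` is the
largest step count whose probability of parsimony still reaches the
chosen limit (90–99%). The probability model: per-site substitution
counts are Poisson with the per-site rate estimated from the observed
difference count through the Jukes–Cantor correction; parsimony holds
when every differing site saw exactly one hit and every identical site
none. `J` is floored at 1 and is non-increasing in the limit. The
original 1992 recursion is not reproduced verbatim here; this estimator
is the package's own documented formulation of the same quantity, and
its values are frozen against an independent straight-line evaluation in
the test suite. Because differences are counted over comparable sites
only, heavily ambiguous sequences connect more easily — the
comparable-site counts are returned so such pairs can be flagged.

**Refined single linkage (RESL-like).** Stage one forms single-linkage
components at a seed threshold (2.2% by default). Stage two evaluates,
inside each component, every candidate split threshold among the
component's own merge heights within a refinement range (0.7%–2.2% by
default) and keeps the split maximising the mean silhouette width over
the component's distance submatrix. An unsplit component has no
silhouette, so "improves on the unsplit component" is operationalised
as: accept the best split only when its mean silhouette exceeds 0.5, the
conventional mark of reasonable structure (configurable). Members of
singleton clusters contribute silhouette 0. This is a locally
reproducible simplification — the database-wide BOLD implementation with
Markov-clustering refinement is intentionally not reproduced, so counts
against BIN-style results are a soft comparison only.

**Concordance.** Each labeled species is classified against a partition:
MATCH (all its specimens alone in one MOTU), SPLIT(k) (k ≥ 2 pure MOTUs),
MERGE (one shared MOTU), MIXTURE(k) (≥ 2 MOTUs, at least one shared).
The categories are exhaustive and exclusive, so their percentages always
total 100% of labeled species. Singletons are classifiable (alone =
MATCH, shared = MERGE).

## Geography

Geographic distances are great-circle (haversine) kilometres on a sphere
of radius 6371 km. Whether the original toolchain used haversine or
projected Euclidean distances is not stated anywhere; haversine is
adopted and logged. The Mantel test correlates the upper triangles of
the genetic and geographic matrices (Pearson), with significance from
simultaneous row/column permutations of one matrix; the observed
statistic is included in the reference set, so `p = (1 + #{r* >= r}) /
(1 + n_perm)` can never be zero and has resolution `1/(n_perm + 1)`.
The default test is one-sided for positive association (isolation by
distance); a two-sided alternative is available by flag. Identical
sampling coordinates are retained as zero distances; a species sampled
at a single site trips the zero-variance guard and is flagged undefined
rather than scored. The screen runs over species with at least 10
individuals spanning at least 275 km, 999 permutations by default.

## Gene trees

Neighbour joining on the full distance matrix, via the standard
agglomeration; on additive matrices the tree's path metric reproduces
the input exactly. Negative branch-length estimates — an expected NJ
artefact on non-additive inputs — are clamped to zero with the deficit
pushed onto the adjacent branches so tip-to-tip paths are preserved,
and each occurrence is reported. Bootstrap support resamples alignment
*columns* with replacement (codon-position agnostic, the distance-based
convention), rebuilds the matrix and the tree per replicate, and scores
each internal bipartition as a percentage of replicates.

## The synthetic-data generator

Every stage is testable without the original sequences because the
generator emulates the statistical structure reported for a large
regional butterfly library:

| parameter | default | what it emulates |
|---|---|---|
| `target_intra_divergence` | 0.003 | ~0.3% mean intraspecific K2P divergence |
| `target_congeneric_divergence` | 0.07 | ~7% mean congeneric divergence |
| `target_intergeneric_divergence` | 0.12 | between-genus divergence staying below saturation |
| `singleton_fraction` | 0.27 | ~27% of species known from one sequence |
| `mean_extra_individuals` | 4.2 | non-singletons 2 + Poisson(4.2), ~4.8 sequences/species overall |
| `alignment_length` | 658 | the standard COI barcode region |
| `ts_tv_ratio` | 3 | transition-biased mitochondrial substitution |
| `divergence_cv` | 0.35 | congeneric distances spreading ~3–14% around the 7% mean |
| `ambiguity_rate` | 5e-4 | a trace of N calls per sequence |

Genus ancestors descend from one root, species ancestors from their
genus ancestor, individuals from their species ancestor; each lineage
receives `Poisson(target × length / 2)` mutation events applied per site
uniformly with multiple hits allowed, so the expected substitution load
between two lineages equals `target × length` — which is exactly what
the K2P estimator recovers, no naive proportion targeting needed. The
gamma multiplier behind `divergence_cv` (mean 1) acts on species- and
genus-level draws only, turning the interspecific distances into a
realistic continuum while leaving the intraspecific pool, and hence the
barcode gap itself, controlled by the targets. Deep intraspecific splits
and shallow interspecific merges are injected on demand
(`split_injections`, `merge_injections`); isolation by distance is
produced by evolving a species serially along a geographic transect, so
nearby individuals share more mutational history. A fixed seed makes the
output byte-identical.

What the generator does **not** emulate: coalescent genealogies within
species, recombination (irrelevant for mtDNA), selection, NUMTs and
contamination, rate variation among sites, and real sampling geography.
Passing tests therefore demonstrate that the algorithms do what they
claim under controlled conditions with known truth — not that any
particular empirical library will behave as cleanly.

## Reproducibility and problem sizes

`run_pipeline()` executes the chain from a single declarative
configuration (strictly validated; unknown keys are errors) and writes
every table, a parameter manifest and a log without timestamps, so one
configuration plus one seed gives byte-identical output. The global seed
fans out to per-stage seeds by a deterministic stage-name hash, so
toggling one stage never shifts another stage's random stream. The
package's interface is its functions and this pipeline;
`scripts/acceptance.R` is the only shell entry point, recomputing the
headline quantities on the synthetic defaults.

The test-suite and acceptance problem sizes are the package's own
choices, picked so each property is measured where it is informative:
libraries of 6–20 species for oracle comparisons, 100 species (~480
sequences) for the headline synthetic run, 100 replicates for threshold
calibration, 500 null replicates at 999 permutations for Mantel
type-I-error calibration, 1000 bootstrap pseudoreplicates, and a
four-point sweep of the intraspecific target for parameter recovery.

## Known limitations

* The RESL-like clusterer is a documented simplification; absolute MOTU
  counts from the BOLD BIN system depend on that database's global
  state and are irreproducible in principle.
* The parsimony connection limit uses the package's own estimator of
  the parsimony probability (above); relative behaviour (monotonicity,
  clustering) is what the analyses rely on, not the absolute `J`.
* ABGD gap detection is a faithful re-implementation of the published
  *idea* with declared internals, not a port of the reference binary;
  partitions can differ near threshold cases.
* Input alignments are taken as authoritative: the package neither
  aligns nor trims, and frame checking assumes the stated frame offset.
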