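---
title: "Residue cluster classes and PPI classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue cluster classes and PPI classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccppi)
```

## The residue cluster class representation

A protein chain of L residues becomes a graph: nodes are residues, and an
edge joins residues i and j whenever the minimum Euclidean distance over
their selected heavy atoms is at most a cutoff c (in Angstrom). The
*residue cluster classes* (RCC) of the chain are the counts of the graph's
maximal cliques of 3 to 6 residues, with each clique classified by how its
members sit along the sequence. A maximal clique is a set of mutually
contacting residues not contained in any larger such set — the densely
packed cores of the fold.

The sequence classification works through integer partitions. Sort a
clique's sequence positions and cut them into maximal runs of consecutive
integers (two positions are "proximal" only when they differ by exactly 1;
residues two or more apart are not). The multiset of run lengths, sorted
non-increasing, is the clique's partition: positions {5, 6, 9} give
[2, 1]; {1, 2, 3} gives [3]; {2, 4, 6} gives [1, 1, 1]. A clique of size k
therefore falls in one of p(k) classes — 3 for k = 3, 5 for k = 4, 7 for
k = 5 and 11 for k = 6 — 26 classes in all, and the RCC of a chain is the
26-vector of clique counts.

```{r classtable}
head(rcc_class_table(), 8)
```

Only the size blocks of the class order are fixed by the representation
(sizes ascending). Within a block this package orders partitions in
descending lexicographic order, so `RCC1` = (3, [3]) and
`RCC26` = (6, [1,1,1,1,1,1]). The ordering is stable and isolated in
`rcc_class_table()`, so an alternative convention could be remapped
without touching the counting logic.

### Decisions the representation itself does not fix

* **Contact criterion.** "Within c Angstrom" is read as the *minimum
  atom–atom distance* over the selected atom sets, inclusive at the
  boundary (d = c is a contact). The minimum-distance convention is the
  one compatible with including or excluding sidechain atoms; it is
  isolated in `build_contact_graph()` so a representative-point variant
  could replace it.
* **Atom modes.** `SC` keeps all heavy atoms; `noSC` keeps the backbone
  set {N, CA, C, O} (standard PDB nomenclature — the carbonyl oxygen is
  part of the backbone). Hydrogens are never used. For glycine both modes
  coincide.
* **Sequence-adjacent residues** (|i − j| = 1) are eligible contacts like
  any other pair; without them the [k] classes of consecutive runs could
  never arise.
* **Cliques larger than 6** fall outside the class table and are
  discarded whole — not truncated or decomposed — so that the vector's
  total remains the count of classified maximal cliques. The number
  discarded is kept in the `n_discarded` field of every `rcc_vector`.
* **Sequence numbering.** Positions used for the proximity partition are
  the sequential indices 1..L after filtering, so gaps in author
  numbering collapse. This is deterministic across files with missing
  residues; `read_structure(..., seq_numbering = "author")` preserves
  author numbering instead for chains where the gap structure matters.
* **Altloc and residue filtering.** One conformer per atom is kept
  (highest occupancy, ties prefer altloc A), waters/heteroatoms and
  non-standard residues (including MSE) are dropped with a warning, and
  only the first model of a multi-model file is read.

Clique enumeration is Bron–Kerbosch with max-degree pivoting over a
degeneracy ordering, with deterministic sorted output. Its correctness is
not taken on faith: the test suite compares it against an exhaustive
subset-enumeration oracle on over a hundred random graphs (n ≤ 13) and
against an independent graph library on larger ones.

## Pair features and scaling

A protein pair is represented either by the elementwise **sum** of the two
RCC vectors (26 features) or by their **concatenation** (52 features).
Both inputs must share cutoff and atom mode. Concatenation keeps the pair
order as given in the input list — no canonicalization — so (A, B) and
(B, A) concatenate differently; this order sensitivity is a documented
caveat and a test, not a hidden assumption.

Three scalings are supported: `raw` (identity), `normalize` (per-feature
min–max to [0, 1]) and `standardize` (per-feature z-score). Scalers are
**fitted on the training partition only** and applied unchanged to test
data; test values outside the training range may legitimately fall outside
[0, 1]. A feature with zero training range (or zero training sd) maps to
the constant 0 rather than NaN, keeping downstream classifiers total.

## Sampling designs

The motivating corpora are heavily imbalanced — hundreds of thousands
of positive pairs against 692 experimentally validated negatives — and
the imbalance is handled by two
strategies, enumerated as a reproducible grid:

* **Undersampling** keeps every negative and draws positives uniformly
  without replacement to exactly 1, 2 or 3 times the negative count.
* **SMOTE oversampling** synthesizes negatives: each synthetic instance is
  x + u (z − x) with x an original minority point, z one of its k = 5
  nearest minority neighbours (Euclidean; the conventional default), and
  one u drawn uniformly on [0, 1) per synthetic instance (classical
  SMOTE — not one u per feature). One unmodified copy of every original
  minority instance is always retained, and the 1:2/1:3 oversamples start
  from the replicate's 1:1 undersample.

The default `sampling_grid_spec()` crosses cutoffs {7, 8} with both atom
modes, both combine modes, three under-ratios, three replicates and three
scalings (216 configurations), plus the two SMOTE factors in place of the
ratios (144), for 360 training configurations, and 2 × 2 × 2 × 3 = 24 test
configurations. Per-configuration seeds are derived deterministically from
the base seed and the configuration tag, so the whole grid is a pure
function of its spec.

Two further operations support leakage control. `split_by_domain()`
implements the majority-to-train constraint: positive pairs are grouped by
the combined domain signature of their proteins, each group sends at most
half of its pairs to test (largest groups processed first), and a repair
pass enforces that no domain occurs more often in test than in train —
so a domain combination seen once can never reach the test set. The
underlying prose rule admits several readings; the greedy reading
implemented here is a deliberate choice, not a claim about any external
pipeline. `remove_redundancy()` dedups feature vectors within each
partition (first occurrence wins, for determinism) and drops test vectors
that exactly match a training vector; `split_negatives()` provides the
non-redundant protocol's seeded 80/20 split of unique negatives.

## Separability diagnostics

`distance_separability()` compares the diameter D of the negative set
(maximum intra-set Euclidean distance) with the smallest inter-set
distance d, and flags the configuration separable-by-distance when
**d > D**: the gap between the classes exceeds the negative set's spread.
This reading is adopted deliberately: a gap smaller than the negative
set's own spread separates nothing, so `d < D` cannot indicate
separation. Because the question is not
fully settled for the positive set, the report also carries the positive
set's diameter.

`linear_separability()` answers the sharper question exactly: does any
hyperplane strictly separate the classes? It solves the hard-margin
feasibility problem (minimise ||w||² subject to y_i(w·x_i + b) ≥ 1) with a
strictly convex QP; the unit margin normalizes scale, so feasibility — not
a tolerance — decides the answer, and the witness (w, b) is re-verified
against every point before being reported. An infeasible system (e.g. the
XOR configuration) reports not separable.

## Feature screening

Whether each RCC position distributes differently in positive and
negative pairs is tested per feature with the two-sided Mann–Whitney
rank-sum test (the appropriate unpaired form for two unequal groups).
Below a combined sample size of 20 the p-value is computed by full
enumeration of all choose(n, n1) rank assignments with tie-averaged ranks
(two-sided via the |S − E S| tail, which on tie-free data coincides with
the classical exact two-sided value); at 20 and above the tie-corrected
normal approximation is used. Raw p-values are corrected across the 26 or
52 features by Bonferroni or Benjamini–Hochberg; the screening level
defaults to alpha = 0.05 and is a parameter. A feature constant across both classes is flagged
degenerate with p = 1 by convention. `nonzero_fraction_profile()` gives
the per-feature fraction of instances with strictly nonzero values — the
profile that motivates concentrating on the 7–8 Angstrom cutoffs, where
the fewest RCC positions are structurally zero.

## The classifier

Locally weighted learning is reconstructed as kernel-weighted k-nearest
neighbours: a query is classified by its k nearest training instances
(Euclidean distance, on the features exactly as scaled — no internal
re-scaling), each weighted by a linear kernel w_i = max(0, 1 − d_i/d_cut)
with d_cut the distance to the (k+1)-th neighbour (or the largest
neighbour distance when k equals the training size); a constant kernel
gives plain kNN. This is the closest open reconstruction of linear-kernel
locally weighted learning; no canonical neighbourhood size exists for
this family, so k is a parameter with default 50. Numerical edge cases are
resolved explicitly: training points tied with the k-th distance all join
the vote (order independence), an all-zero weight vector falls back to a
constant vote over the same neighbours, and exact vote ties resolve to
the negative class — the conservative direction in a domain where
positives dominate. Both tie rules are configurable consequences of the
implementation, covered by tests.

Evaluation reports %CCI = 100 (TP + TN)/N on both partitions and the
difference delta = CCI_test − CCI_train. Model selection ranks
configurations by CCI_test descending, then |delta| ascending, then label
— the "top right corner" of the selection scatter, preferring accurate
models with no train/test gap.

## The synthetic-data generators

Real structure corpora and curated interaction databases are external
inputs this package never downloads, so its test bed is synthetic and
fully seeded:

* `generate_chain()` emits pseudo-CA chains with exact 3.8 Angstrom
  consecutive spacing — a self-avoiding random walk (excluded-volume
  radius 3.0 Angstrom), an ideal alpha-helical trace, or a straight
  extended chain — optionally with pseudo-CB atoms offset 1.5 Angstrom.
  CA-only fixtures make SC and noSC coincide unless sidechains are
  requested, keeping geometric oracles hand-checkable (an extended chain
  has no triangles at 4 Angstrom; its first clique appears once the
  cutoff spans two bonds).
* `generate_contact_graph()` gives seeded Erdos–Renyi graphs for the
  clique machinery.
* `generate_ppi_dataset()` emulates RCC count statistics for classifier
  tests: independent Poisson features with exponentially decaying base
  rates (heavy mass at small counts), a class-conditional mean shift
  delta added to the first 10 features for positives, and the trailing
  15 % of features structurally zero in both classes, mirroring the
  sparse high-index classes of real profiles; 70/30 train/test split,
  n = 200 per class in the recovery experiments.

These generators emulate the *count statistics and geometry* the pipeline
consumes, not biology: there are no Ramachandran constraints, no real
fold topology, no correlation structure between features, and no sequence
similarity between "pairs". Passing tests therefore demonstrate that the
machinery is correct and that the classifier recovers a known
class-conditional signal (CCI rises monotonically from ~50 % at delta = 0
to ≥ 95 % at delta = 8) — they do not certify accuracy on real interaction
data, which requires the external corpora.

## Problem sizes and reproducibility

The suite and the acceptance script run at desk scale by choice: random
graphs up to 13 nodes against the exhaustive subset oracle (the oracle is
exponential; 13 nodes keeps it exact and quick), 20-residue chains against
brute-force distance scans, exact rank-sum enumeration up to a combined
n of 12, and 3 replicates of 200-instances-per-class recovery runs. Every
stochastic operation takes an explicit seed, sub-seeds are derived
deterministically from (base seed, configuration tag), and each CLI
subcommand writes a JSON manifest from which `rccppi rerun` reproduces its
outputs byte for byte.

## Known limitations

* One chain per structure; no inter-chain (interface) contact maps, no
  symmetry mates, no missing-atom repair.
* The within-size class order and the >6-clique policy are conventions;
  both are isolated behind `rcc_class_table()` for remapping.
* The locally-weighted-learning reconstruction approximates tooling whose
  exact kernel and neighbourhood defaults are not recoverable; headline
  accuracies from the original corpora are out of scope by design.
* Concatenation-order sensitivity is surfaced, not resolved: callers who
  need symmetry should canonicalize pair order upstream.
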