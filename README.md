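# rccppi

Residue cluster classes (RCC) for protein–protein interaction (PPI)
modeling.

## The problem

Whether two proteins interact is written, in part, into their 3D
structures — but machine learning needs a numeric representation of
structure that is compact, comparable across proteins of different
length, and informative about packing. `rccppi` implements such a
representation and the classification pipeline built on it, for
structural bioinformaticians who want to featurize chains from PDB files
and model interaction labels on protein pairs.

## The representation

A chain of L residues becomes a contact graph: nodes are residues, and an
edge joins residues *i*, *j* when the minimum distance over their selected
heavy atoms (all heavy atoms, or backbone N/CA/C/O only) is ≤ *c* Å, for a
cutoff *c* ∈ {4, …, 15}. The **residue cluster class vector** counts the
graph's maximal cliques of sizes *k* = 3–6, each classified by the integer
partition of *k* induced by maximal runs of consecutive sequence positions
within the clique: clique positions {5, 6, 9} → partition [2, 1]. The
3 + 5 + 7 + 11 = 26 (size, partition) classes give a 26-dimensional count
vector per chain:

    RCC(P; c, mode) = ( #cliques in class 1, …, #cliques in class 26 )

A protein pair is represented by the elementwise **sum** (26 features) or
the **concatenation** (52 features) of its two RCC vectors, optionally
min–max normalized or standardized with statistics fitted on training
data only. On top of that sit the study-design tools: undersampling /
SMOTE oversampling grids (216 + 144 = 360 training configurations, 24
test configurations under the default spec), domain-aware train/test
splitting, redundancy removal, separability diagnostics (negative-set
diameter *D* vs inter-set distance *d*; exact hard-margin linear
separability), per-feature rank-sum screening with Bonferroni/BH
correction, and a kernel-weighted k-nearest-neighbour classifier
evaluated by %CCI (percent correctly classified instances).

## Worked example

```r
library(rccppi)

# two synthetic pseudo-CA chains stand in for PDB inputs
s1 <- generate_chain(chain_spec(40, seed = 101))
s2 <- generate_chain(chain_spec(35, seed = 202))

rcc_from_structure(s1, cutoff = 7, atom_mode = "noSC")
#> rcc_vector synthchain101_A (cutoff 7 A, noSC)
#>  RCC1  RCC2  RCC3  RCC4  RCC5  RCC6  RCC7  RCC8  RCC9 RCC10 RCC11 RCC12 RCC13
#>     4     1     1     5     8     1     0     0     1     5     3     1     0
#> RCC14 RCC15 RCC16 RCC17 RCC18 RCC19 RCC20 RCC21 RCC22 RCC23 RCC24 RCC25 RCC26
#>     0     0     2     0     0     0     0     0     0     0     0     0     0
```

The 40-residue chain packs 4 maximal triangles of three consecutive
residues (RCC1 = 4, class (3, [3])), 8 four-residue cliques of pattern
[2, 2] (RCC5), and so on; high-index six-residue classes are empty, as
they typically are at this cutoff. Pair features and a classification run
on a synthetic labeled dataset:

```r
pair <- combine_rcc(rcc_from_structure(s1, 7, "noSC"),
                    rcc_from_structure(s2, 7, "noSC"), mode = "sum")
pair[1:8]
#> RCC1 RCC2 RCC3 RCC4 RCC5 RCC6 RCC7 RCC8
#>   12    5    1    7    8    1    1    0

sets  <- generate_ppi_dataset(ppi_sim_spec(200, 200, shift = 4, seed = 7))
model <- fit_lwl(sets$train, k = 25, kernel = "linear")
evaluate_model(model, sets$train, sets$test, label = "shift4_k25")
#> eval_report shift4_k25
#>  CCI train 100.0%  test 99.2%  delta -0.8
#>  test confusion: TP 59  TN 60  FP 0  FN 1
```

A class-conditional mean shift of 4 counts on 10 features is recovered
almost perfectly (99.2 % of test instances correctly classified, one
false negative), with a 0.8-point train/test gap. Screening confirms the
signal sits where it was planted — exactly the 10 shifted features are
significant after Benjamini–Hochberg correction:

```r
scr <- feature_screen(sets$train$features[sets$train$labels == "positive", ],
                      sets$train$features[sets$train$labels == "negative", ],
                      correction = "bh")
sum(scr$significant)
#> [1] 10
```

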