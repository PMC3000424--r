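---
title: "Predicting subcellular localization from partial peptides: models, protocol, and design choices"
author: "peploc developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting subcellular localization from partial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Expressed sequence tags (ESTs) are single-pass cDNA reads of roughly 600
nucleotides. Conceptually translated, they yield *EST-peptides*: partial
protein sequences of ~200 residues that frequently lack the protein's
N-terminus — and with it the targeting signal most localization predictors
rely on. Tools trained on full-length proteins degrade badly on such input.
`peploc` implements a predictor designed for this regime: it learns
compartment membership from global sequence statistics that survive
truncation, rather than from positional signal anatomy.

The predictor distinguishes nine compartments: chloroplast (chl), cytosol
(cyt), endoplasmic reticulum (end), extracellular space (ext),
mitochondrion (mit), nucleus (nuc), peroxisome (per), plasma membrane
(pla), and vacuole (vac).

## Feature representations

Forty-one representations of a peptide are registered, in a frozen order
(`build_feature_registry()`):

1. **Physicochemical summary** (1 spec). Each amino-acid index from an
   AAindex1-format table contributes one coordinate: the index value summed
   over the residues and normalized. With the classic 494-entry snapshot
   this is a 494-dimensional vector. *Numerical choice*: indices with
   missing (`NA`) residue values are normalized by the number of residues
   they actually cover, so a partially defined index is an average over the
   residues it knows rather than being diluted by sequence length. An index
   covering no residue of a sequence contributes 0 and logs a warning.
2. **k-th order composition** (22 specs). Frequencies of overlapping
   k-mers, divided by the window count $L-k+1$: ungrouped alphabet for
   $k = 1..6$, and two reduced alphabets for $k = 1..8$ — group C
   (8 chemical groups: acidic DE, basic HKR, aromatic FWY, small-hydroxyl
   ST, sulphur CM, aliphatic AGP and ILV, amide NQ) and group D (10
   structural groups). Orders stop at 6 (ungrouped) and 8 (grouped) because
   higher orders overfit. A sequence shorter than $k$ yields a zero vector
   with a warning, not an error: genuine EST-peptides vary in length.
3. **Gapped pair composition** (18 specs). Frequencies of ordered symbol
   pairs separated by exactly $x$ intervening residues (positions $i$ and
   $i+x+1$), $x = 1..6$, on each of the three alphabets, normalized by
   $L-x-1$. *Design choice*: "separated by $x$ residues" is read as exactly
   $x$ intervening residues and the pairs are ordered; both conventions are
   stated here because the source description leaves them open.

Vectors for spaces up to 10,000 keys are laid out over the fully enumerated
key space; larger spaces ($20^4 = 160{,}000$ up to $20^6 = 64$ million)
store only observed keys, sorted — a sequence of length $L$ can occupy at
most $L-k+1$ of them, so sparse storage is mandatory and dense allocation
is never attempted. At prediction time, keys unseen in training are
dropped; for an RBF kernel this scales all kernel evaluations of the query
by a common factor and cannot flip a binary decision.

## The classifier

Each representation feeds a one-vs-one multi-class soft-margin classifier
with the RBF kernel $K(x_i,x_j) = \exp(-\gamma\|x_i-x_j\|^2)$. Because the
deployment environment provides no SVM library, the C-SVC dual is solved by
a sequential-minimal-optimization solver implemented in this package
(`src/smo.cpp`): second-order working-set selection, pair updates with box
clipping, stopping when the maximal KKT violation falls below `eps`. The
test suite pins the solver against an exact quadratic-programming oracle
(`quadprog`) on small problems.

Class probabilities follow the classical two-step recipe: a Platt sigmoid
$P(y=1\mid f) = 1/(1+e^{Af+B})$ is fitted per binary machine on decision
values from an internal 5-fold cross-validation (fitting on in-sample
decision values would produce degenerate step-like sigmoids on separable
data), and the $\binom{k}{2}$ pairwise probabilities are coupled into a
$k$-class distribution by the standard fixed-point iteration. Probability
outputs are equivariant under class relabeling only up to the calibration
folds' dependence on class order — the same caveat the reference
implementations carry.

Features are affinely scaled to $[0,1]$ per dimension before the kernel;
AAindex coordinates live on arbitrary scales and would otherwise dominate.
The scaler is part of the model and is fitted **only** on training rows; a
dedicated test asserts that evaluation rows never influence it.

### Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| C | misclassification penalty | grid-searched over $2^{-5},2^{-3},\dots,2^{15}$ | the conventional log2 grid; the source protocol does not report its grid |
| $\gamma$ | RBF width (1/feature-units²) | grid-searched over $2^{-15},\dots,2^{3}$ | same convention |
| eps | SMO stopping tolerance | $10^{-3}$ final fits, $10^{-2}$ inner fits | inner fits only rank grid points; see "compute budget" |
| folds | outer × inner | 10 × 10 | the nested protocol's stated design |

Model selection uses mean inner-fold overall accuracy (the selection
criterion is unnamed in the source; overall accuracy is the natural
reading), ties broken toward smaller C then smaller $\gamma$ —
deterministic and biased toward smoother models.

## The nested 10-fold protocol

The dataset is split into 10 outer folds (stratified by class by default:
with 5-member classes in real data, plain random folding regularly produces
class-free folds; a plain mode is available). For each outer fold, a 10-fold
grid search runs **only** on the outer-training data, the model is refitted
on all outer-training records with the selected $(C,\gamma)$, and the
held-out fold is predicted. Per-fold confusion counts yield per-class
sensitivity, specificity, positive predictive value and Matthews
correlation, reported as mean(SD) over folds — sample SD with $n-1$
denominator; a single fold reports SD 0. Metrics with zero denominators are
reported as 0 with an `undefined` flag: a class never predicted prints as
0, it does not crash the report.

## Feature integration

Three scheme kinds (`scheme_spec()`):

- **single_feature** — one representation, one classifier;
- **concat_attributes** — member vectors concatenated in registry order;
- **stacked_predictions** — one probability-emitting classifier per member;
  their class-probability blocks concatenated (member order × class order)
  into a meta-vector of size |members| × |classes| (369 for all 41 members
  over 9 classes) that feeds a second-layer classifier.

*Design choice*: the second layer trains on the first layer's **in-sample**
probabilities of its own training records. Out-of-fold first-layer
predictions would reduce the optimism of the meta-features, but the simpler
in-sample variant is the documented baseline here; the distinction matters
for overfitting and is deliberately surfaced rather than hidden. The
historically best-performing member triple — ungrouped 4th-order, group-C
6th-order, group-D 7th-order composition — is available as
`top3_members()`.

## Training-set expansion

When EST-derived training data are scarce, full-length proteins are broken
into EST-like fragments: proteins under 200 residues pass unchanged;
200–400 residues yield an N-terminal fragment (starting uniformly within 80
residues downstream of the first methionine; position 1 if none) and a
C-terminal fragment ending at the last residue; beyond 400 residues a
central fragment is added, starting uniformly after the first 80 residues
but before the sequence midpoint. Fragment lengths are uniform on 140–260
residues (an EST length survey: ~600 nt mean, ~180 nt SD, divided by 3),
clipped to the available residues — clipping, never erroring, also covers
the tight central interval at lengths just over 400. Uniform draws are a
choice; the source states ranges, not distributions.

The pooled fragments and EST-peptides then pass greedy redundancy
reduction: records are visited longest-first and kept only if no
already-kept record exceeds 60% identity, where identity is Smith–Waterman
local alignment matches (match +1, mismatch −1, gap open −2, gap extend −1)
over the shorter sequence length — the short-sequence-normalized notion
greedy clustering tools use, with exhaustive pairwise checking in place of
a word filter, which is fine at desk scale.

## The synthetic-data generator

`generate_dataset()` emits labeled EST-peptide-like records: lengths from a
normal(200, 60) truncated to [50, 600] residues; each class's residue
distribution drawn from a symmetric Dirichlet and mixed with the uniform
background as $s\cdot\text{class} + (1-s)\cdot\text{uniform}$, with
`signal_strength` $s \in [0,1]$; optional class-specific tetra-peptide
motifs inserted at a configured per-record rate. The compositional channel
is learnable by even 1st-order features; the motif channel only by $k\ge4$
composition — operationalizing the question of where tetra-peptide
information lives.

What the generator does **not** emulate: real targeting-signal anatomy,
transmembrane segments, homology structure between records, or
class-imbalance profiles of curated data. A green synthetic test therefore
establishes that the pipeline's machinery is correct and recovers planted
signal — not that the historical accuracies on curated plant data are
reproduced. Those depend on a 1,477-sequence harvest that cannot be
reconstructed offline and are outside this package's acceptance surface.

## Compute budget and numerical behavior

- Grid-search inner fits use SMO tolerance 0.01 and an iteration cap of
  100×(training size). The huge-C/tiny-$\gamma$ grid corners otherwise
  consume minutes for fits that never win selection; the refit with the
  selected parameters always runs at tolerance $10^{-3}$ with a $10^6$
  iteration ceiling. The acceptance tests run the thinned 6×5 version of
  the default grid for the same reason — a compute choice, fixed before the
  expectations were frozen.
- On null data (signal 0), nested accuracy sits near the 33.3% 3-class
  chance level but fluctuates widely across seeds and can dip **below**
  chance: hyperparameter selection on noise plus the negative train/test
  correlation of cross-validation produces the well-documented
  below-chance bias of this protocol. The acceptance band (chance ± 15
  percentage points) covers both this bias and the Monte-Carlo error of
  150 dependent predictions; the acceptance test computes the actual value
  at its fixed seed.
- Degenerate inputs are defined, not fatal: sequences shorter than the
  window give zero vectors with warnings; zero-denominator metrics report
  0 with a flag; vote ties break toward the first class in canonical order.

## Known limitations

- The in-sample stacking variant can overstate second-layer confidence.
- `best_frame_translate()` is labeled plumbing: a six-frame longest
  stop-free-stretch heuristic, not an ORF predictor; the CLI requires an
  explicit `--translate` flag before using it.
- Exhaustive pairwise clustering is quadratic; it replaces a word-filtered
  tool and is meant for datasets of hundreds, not hundreds of thousands.
- No class weighting: minority-class sensitivity is expected to be poor on
  imbalanced data — the method is reproduced, not repaired.
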