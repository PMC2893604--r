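---
title: "Predicting caspase cleavage sites: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting caspase cleavage sites: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pripper)
```

## The prediction problem

Caspases cleave their substrates at the peptide bond C-terminal to a
P4P3P2P1 recognition motif, with Asp at P1 in the overwhelming majority of
sites. Because the motif is only moderately conserved, classifying a
candidate position as cut/not-cut requires the flanking sequence context on
both sides of the scissile bond. `pripper` treats this as supervised binary
classification over fixed-geometry residue windows:

* a **candidate site** is the 1-based index of a P1 residue; the cut falls
  between P1 and P1';
* a **window** of geometry `(n_left, n_right)` takes the `n_left` residues
  ending at P1 and the `n_right` residues from P1' onward;
* each residue becomes a 20-element one-hot block, so a `(6, 4)` window is
  a 200-dimensional sparse binary vector.

The residue-to-index table is frozen package-wide (`aa_residues()`; Val
first, Ala fifth). Any such table yields an equivalent classifier, since a
different table merely permutes feature columns; the test suite asserts
this symmetry explicitly (exactly for the SVM and the CART tree, and as a
high-agreement check for the forest, whose per-split feature sampling
depends on column order and is therefore only invariant in distribution).

## Classifiers and their tuning

Three classifier families are supported, each with an optimised default
window and hyperparameters exposed through `classifier_config()`:

| algorithm | window | key parameters |
|---|---|---|
| `svm` (ν-SVC, RBF) | 6-4 | γ = 2^-5.5 ≈ 0.0221, ν = 0.536, tolerance 1e-5 |
| `random_forest` | 12-12 | 143 trees, 4 features per split, unlimited depth |
| `decision_tree` (CART) | 4-2 | ≥ 5 objects per leaf, binary splits, cp = 0.01 |

Notes on the mapping onto the backing libraries:

* The SVM is fitted by libsvm through `e1071::svm` with `scale = FALSE`:
  one-hot columns are already commensurate, per-column standardisation
  would distort the RBF geometry (and γ's meaning) and slows convergence
  markedly. γ is computed as `2^-5.5`, never hard-coded as a decimal.
* The forest is fitted by `ranger`, whose implementation of Breiman's
  algorithm is fast enough to make full leave-one-out protocols (hundreds
  of refits) routine on one CPU. The decision score is the fraction of
  trees voting positive.
* The decision tree is a CART tree (`rpart`). Error-based
  confidence-factor pruning of the C4.5/J48 family has no exact CART
  equivalent; the complexity parameter `cp` plays the role of pruning
  strength, `minbucket = 5` maps the minimum-objects constraint, and
  binary splits are inherent to CART. C4.5-specific flags passed in
  `params` are kept as metadata only. One family-level property survives
  the translation and is asserted in the tests: when every negative
  example carries Asp at P1 by construction, the P1 slot is uninformative
  and never appears as a split.

Decision thresholds default to each algorithm's native operating point
(signed margin 0 for the SVM, positive-vote fraction 0.5 for the tree
methods). `grid_search()` reruns the leave-one-out protocol over the
model-selection grid (`n_left` in 4–16, `n_right` in 0–16, step 2),
breaking accuracy ties toward the smaller window and then grid order.

The **Vote** ensemble labels a site positive only under a strict majority;
with the default SVM + RF pair both members must agree. Members apply
their own geometries; a member whose window overruns a terminus under the
`skip` policy abstains, and abstentions count as negative votes — the
conservative choice for an ensemble whose role is raising precision.

## Datasets: real format and synthetic generator

`build_dataset()` mirrors how curated caspase training sets are
constructed: positives are annotated P1 positions; negatives are drawn
from non-annotated Asp positions *of the same proteins*, so the P1 residue
itself carries no class signal. The default policy samples negatives
uniformly (seeded) to a balanced 1:1 ratio; an exhaustive mode keeps all
eligible negatives, since curated sources rarely state their selection
rule. Duplicate windows are removed, and a window occurring under both
labels keeps only its positive copy.

`generate_synthetic_corpus()` emulates such a set without any external
download. Proteins are i.i.d. uniform over the 20 residues; planted
positives overwrite a P4–P1 motif drawn from the three canonical caspase
classes at weights 0.5 / 0.25 / 0.25 (DEXD-type sites, contributed by the
abundant executioner-caspase substrates, are given the largest share), and
the P1' position is drawn from G/A/S with probability 0.5 (small residues
after the scissile bond are a known, learnable secondary signal). Defaults
are 1.25 planted sites per protein (Poisson) on proteins of 60–200
residues, echoing the roughly 1.2 annotated sites per protein of curated
collections.

What the generator does *not* emulate: compositional bias of real
proteomes, homology between substrates, motif degeneracy beyond the three
classes, and the fact that curated negatives come from proteins known to
be cut elsewhere. Planted signal is strong and nearly noise-free, so
classifiers reach accuracies in the high nineties here; passing these
tests validates the machinery (encoding, training, protocols,
combinatorics), not the expected accuracy on curated biological data,
which is substantially lower. The evaluation pipeline accepts any curated
set supplied in the package's on-disk format via `read_training_set()`
(a FASTA of proteins plus a TSV of positive P1 positions; a synthetic
stand-in ships in `inst/extdata/`).

## Evaluation protocols

* **Leave-one-out** (`leave_one_out()`): the model is refitted N times
  with fixed hyperparameters, each time classifying the held-out site.
  This is the honest small-sample protocol when every annotated site is
  precious; the implementation is the plain refit loop, and a test pins
  it against an independently coded loop. Folds that lose a class (tiny
  datasets) predict the training majority with a warning by default.
* **Quality measures** (`quality_measures()`): ACC, PRC, FDR = 1 − PRC,
  SPC and MCC from the confusion counts. With no positive predictions PRC
  and FDR are undefined and reported as `NaN` with a flag; a zero MCC
  denominator yields 0 by the standard convention.
* **ROC/AUC** (`roc_points()`): thresholds at every distinct score,
  endpoints (0,0) and (1,1), trapezoid AUC; ties handled so the AUC
  equals the Mann–Whitney pair-counting estimator (asserted against both
  that estimator and `pROC`). The Vote has no threshold to sweep, so it
  is reported as a single operating point, not a curve.
* **Bootstrap comparison** (`bootstrap_compare()`): 10 000 resamples of
  the evaluation set with replacement; each fixed-threshold classifier is
  evaluated per replicate and its (FPR, TPR) mean ± SD reported.
  Resampling is realised as multinomial replicate weights — exactly the
  index-resampling distribution, but vectorisable so the default replicate
  count runs in seconds. Replicates that lose a class are skipped and
  tallied. Whether "the original test set" should be the LOO predictions
  or a held-out split is left to the caller; the package default pipes the
  LOO predictions in, which uses every annotated site.

## Digestion semantics

Cuts fall C-terminal to each predicted (or user-supplied) P1. For `k`
cuts the three modes produce: `single_site` the 2k one-cut-at-a-time
flanking products (a cut after the final residue contributes only its
intact left product); `all_sites` the k+1 simultaneous fragments, whose
in-order concatenation reconstructs the parent exactly; and
`all_combinations` every fragment from any subset of cuts — equivalently
every span bounded by termini or cuts, (k+1)(k+2)/2 spans including the
intact sequence (the empty subset). Identical spans are emitted once
(search engines dislike duplicate entries); provenance headers make every
product traceable to its parent, span, cut positions and P4–P1 context.
`min_fragment_length` (default 1) can drop fragments too short to yield
identifiable peptides. Known-site lists bypass prediction per protein
entirely. `summarize_product_fasta()` recomputes the run statistics from
the written database as an audit.

Terminal windows during proteome scanning are zero-padded (`pad`) so
near-terminal Asp residues are still evaluated — an all-zero block is
"no information", which the classifiers handle gracefully — whereas
training uses `skip`, since curated windows are complete by construction.
Both policies are explicit options on every entry point.

## Numerical and degenerate-input choices

* Non-standard residue codes (B, Z, X, U, O, J, `*`) are rejected by
  default with the offending record and position named; `relaxed = TRUE`
  maps them to the placeholder `X`, which encodes as an all-zero block.
  Rejection is the safe default for models trained on the 20-letter
  alphabet.
* All stochastic steps (negative sampling, corpus generation, forest
  training, splits, bootstrap) take explicit seeds and restore the
  caller's RNG state; fixed defaults make every documented pipeline
  reproducible end to end.
* Model bundles (`save_model()`) embed the residue table and geometry and
  refuse to load under a mismatched encoding; prediction validates input
  width against the stored geometry.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at deliberately scaled
study sizes chosen once: the signal-recovery study uses 380 synthetic
proteins (~400 usable planted positives after terminal-window skipping at
the widest geometry, balanced 1:1), full LOO for all three classifiers;
grid-search checks use a 4-cell grid on a small corpus; the digestion
smoke test uses a 1 000-protein proteome with the SVM+RF Vote; the
bootstrap uses the full 10 000 replicates. On one CPU the whole suite
completes in a few minutes.

## Known limitations

* CART is not C4.5: tree shapes and the tree's LOO figures will differ
  from an exact J48 at the same nominal settings.
* Windowed primary sequence only — no structural accessibility, disorder
  or PEST-region features, which are known to refine cleavage prediction.
* The synthetic generator's independence assumptions make its accuracies
  optimistic relative to curated data (see above).
* `all_combinations` grows quadratically in the number of cuts per
  protein; for heavily cut proteins prefer `single_site` (the default,
  and the biologically motivated choice, as substrates are typically cut
  once per molecule).
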