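---
title: "Predicting miRNA-disease associations with scplpa: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations with scplpa: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scplpa)
```

## The problem

Experimentally validated miRNA-disease associations are sparse: catalogues
such as HMDD record a binary matrix `MD` (miRNAs on the rows, diseases on the
columns) in which the overwhelming majority of pairs are simply untested.
The task is positive-unlabelled link prediction: rank the unknown pairs so
that the pairs most likely to be true associations come first. The guiding
assumption is the usual one in this field — functionally similar miRNAs tend
to be associated with phenotypically similar diseases — so the predictor is
built entirely from two similarity networks and the known links.

## The model

The pipeline has three stages.

**1. Heterogeneous similarity networks.** On the disease side, semantic
similarity is computed from MeSH-style ancestor DAGs in the
information-content form: an ancestor term `t` contributes
`D(t) = -log(k_t / N)` where `k_t` is the number of disease DAGs containing
`t` and `N` is the disease universe size; the semantic value of a disease is
`DV(d) = sum over N(d) of D(t)` (with `N(d)` the ancestor set, `d`
included), and

```
DD(i, j) = sum over t in N(i) ∩ N(j) of 2 D(t) / (DV(i) + DV(j)).
```

Because sparse hierarchies leave many zero entries, a Gaussian interaction
profile (GIP) kernel over the association columns is blended in by simple
averaging: `DDf = (DD + GD) / 2`. On the miRNA side, functional similarity
scores two miRNAs by the best semantic matches between their associated
disease sets (`MM`), and the GIP kernel over association rows substitutes
wherever `MM` is exactly zero: `MMf(i,j) = MM(i,j)` if nonzero, else
`GM(i,j)`. The GIP bandwidth is data-driven: the reciprocal mean squared
profile norm, so an average profile has unit kernel length scale.

**2. Label propagation.** Each network is normalized by the degree-sum rule
`W*(i,j) = W(i,j) / (rowsum_i + colsum_j)`, which for symmetric nonnegative
`W` bounds every row sum by 1 and hence guarantees a contraction. The known
labels are diffused by

```
F_{t+1} = (1 - a) W* F_t + a Y,   F_0 = Y,
```

on the disease network with `Y = t(MD)` (restart weight `alpha`) and on the
miRNA network with `Y = MD` (weight `beta`), iterated until the max-abs
change drops below the tolerance. The two fixed points are blended into the
estimated scores `Fe = (1 - delta) t(FD) + delta FM`, all in miRNA x disease
orientation.

**3. Network consistency projection.** The estimated scores are refined by
projecting each similarity vector onto the corresponding score vector,
normalized by its Euclidean length:

```
MDpm(i,j) = MMf[i, ] . Fe[, j] / ||Fe[, j]||
MDpd(i,j) = DDf[j, ] . Fe[i, ] / ||Fe[i, ]||
MD*       = epsilon MDpm + (1 - epsilon) MDpd.
```

Intuitively, a pair scores high when miRNAs similar to `i` already score
high for disease `j` (and symmetrically on the disease side), with the norm
making the projection invariant to the overall scale of each score slice.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `alpha`, `beta` | restart weight of the two propagations (share of the original labels re-injected each step); in (0, 1] | 0.9 |
| `delta` | share of the miRNA-network propagation in `Fe`; in [0, 1] | 0.9 |
| `epsilon` | share of the miRNA-side projection in `MD*`; in [0, 1] | 0.6 |
| `tolerance` | propagation stopping rule (max-abs change) | 1e-6 |
| `max_iterations` | propagation cap; hitting it flags non-convergence | 1000 |
| `log_base` | information-content logarithm | natural |
| `normalization_mode` | `degree_sum` or `symmetric` | `degree_sum` |

The defaults are the optimum of the sequential sweep protocol implemented in
`parameter_sweep()`: sweep `alpha = beta` at `delta = epsilon = 0.5`, then
`delta`, then `epsilon`, each by leave-one-out AUC. With `alpha = 0.9` the
iteration contracts by a factor 0.1 per step, so propagation converges in a
handful of iterations; smaller restart weights diffuse further but converge
more slowly.

## Design choices where the design was open

* **Normalization.** The degree-sum rule is the default because it provably
  bounds row sums (hence the spectral radius) by 1 for any symmetric
  nonnegative input, making convergence unconditional. The symmetric
  `D^{-1/2} W D^{-1/2}` variant, common in the label-propagation literature,
  is available as a config switch; it bounds the spectral radius but not the
  row sums.
* **Orientation.** Both projections (and the final scores) are emitted in
  miRNA x disease orientation, which is the only shape-consistent
  composition of the three stages; `project_disease()` offers a
  disease-major orientation flag for users who prefer the transposed form.
* **Threshold for ACC/MCC/F1.** Classification metrics need a score cutoff,
  and ranking methods do not define one naturally. The default is the
  threshold maximizing Youden's J (TPR - FPR) on the ROC, with a fixed-value
  override in `scplpa_config()`. Reported ACC/MCC/F1 values are therefore
  comparable only under the same threshold rule.
* **F1.** The standard harmonic mean `2PR / (P + R)` is used.
* **Similarity refresh inside cross-validation.** In `loocv()` the semantic,
  functional and kernel similarities are computed once from the full matrix
  by default; `refresh_gip_per_fold = TRUE` recomputes the kernels inside
  each fold (the functional similarity stays fixed, emulating a
  literature-derived matrix). In `leave_one_entity_out()` the kernels are
  *always* refreshed — the held-out entity's profile is empty, and using
  full-data kernels would leak the very links being predicted — while the
  functional and semantic similarities stay fixed. Note the systemic caveat:
  keeping `MM` fixed mirrors how published evaluations use an external
  functional-similarity matrix, and shares that protocol's mild circularity.
* **Zero guards.** Zero-norm score slices project to 0 (never NaN), empty
  disease sets give zero functional similarity off the diagonal, and
  degenerate semantic pairs (only universal ancestors) get similarity 0 with
  a warning. These keep cross-validation folds rankable even when masking
  empties a row or column.
* **Ties.** ROC/PR sweeps group tied scores (a tie contributes a diagonal
  segment, equivalently one half per tied pair); prediction tables break
  score ties lexically by miRNA then disease name so output files are
  reproducible byte for byte.

## The synthetic benchmark

`generate_fixture()` plants the structure the model assumes. miRNAs and
diseases are partitioned into aligned blocks; pairs inside a block link with
probability 0.6, across blocks 0.03 (defaults: 40 miRNAs, 25 diseases, 4
blocks, overall density about 0.18). Each disease block carries its own
rooted ancestor tree (disjoint across blocks), with diseases placed at
depths 1-3 and occasional extra parents, so within-block disease pairs share
ancestors (positive semantic similarity) and cross-block pairs share none.
All draws run through a single integer seed, and labels are emitted in
sorted order, so every fixture is reproducible bit for bit.

The sizes were chosen so that a full leave-one-out run (one pipeline fit per
known link, roughly 180 fits) completes in well under a second, which is
what makes seed-averaged protocols and the sequential sweep practical.

What the fixture does *not* emulate: the scale-free degree distribution of
real catalogues, overlapping disease hierarchies (MeSH terms shared across
branches), noise in the DAGs, or any biological content in the names.
Passing the planted-signal tests shows the pipeline recovers
block-structured signal aligned with the semantic hierarchy; it does not
certify performance on real HMDD-scale data.

A caution on evaluation: a global leave-one-out protocol rewards degree —
held-out positive cells over-represent high-degree rows and columns, and a
profile-kernel pipeline ranks high-degree pairs first. Even on a uniformly
shuffled matrix the harness therefore scores well above 0.5, which is why
the acceptance script reports the shuffled-matrix control alongside the
real AUC: the meaningful quantity is the contrast, with the control as the
degree-bias floor.

## Numerical notes

* Propagation convergence is measured by the max-abs elementwise change;
  with the default tolerance `1e-6` and `alpha = 0.9` the fixed point
  matches the closed-form linear solve to about `1e-8` (tested against
  `solve()` on random instances).
* Kernel distances are computed via `outer(sq, sq, "+") - 2 tcrossprod(P)`
  and clamped at 0 to absorb floating-point negatives; kernel diagonals are
  set to exactly 1.
* Similarity constructors enforce symmetry to `1e-12` and clamp entries into
  `[0, 1]`.
* Non-convergence at the iteration cap warns and flags the result rather
  than failing, so parameter exploration at small restart weights remains
  possible.

## Known limitations

* Predictions are biased toward well-annotated entities (high-degree rows
  and columns) — inherent to propagation on profile-derived kernels.
* Cold-start miRNA prediction relies entirely on the fixed functional
  similarity; for a miRNA absent from it (and with no associations) the
  zero-profile kernel is anti-informative.
* The semantic similarity implements the information-content form only; the
  decay-factor (Wang-style) contribution is out of scope.
* The evaluation harness assumes all unknown pairs are negative, the usual
  positive-unlabelled approximation; reported AUPR in particular should be
  read as a lower bound.
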