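---
title: "A desk-scale living benchmark for single-cell analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale living benchmark for single-cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbench)
```

## The component model

scbench organises benchmarking of single-cell analysis methods around a
three-part component model. A **task** is a defined analysis problem —
denoising, label projection, batch integration — assembled from three kinds
of single-function components:

* **datasets** build a `cbg_dataset` (an annotated cell-by-gene count
  container) carrying the task's ground truth, from `(test_mode, seed)`;
* **methods** take the dataset and return it with output slots filled;
* **metrics** take a method's output and return one real number, tagged
  with an orientation (maximize or minimize).

The runner evaluates every method on every dataset with every metric.
Failures are isolated per (dataset, method): a crashing method records
missing values for its metrics and the run continues, which is what a
continuously extended benchmark needs to survive one bad contribution.

## Baseline-anchored normalization

Metrics have incomparable ranges, so overall rankings would otherwise be
dominated by whichever metric happens to have the widest spread. Every task
therefore registers two **control (baseline) methods**: a positive control
approximating the best achievable output (for example, copying the true
labels) and a negative control approximating random performance. Per
(dataset, metric), raw scores are oriented so larger is better, and the
controls' oriented scores define the anchors:

$$\tilde s = \frac{s - s_{\min}^{\mathrm{ctrl}}}{s_{\max}^{\mathrm{ctrl}} - s_{\min}^{\mathrm{ctrl}}}$$

so the optimum-achieving control maps to exactly 1 and the
minimum-achieving control to exactly 0. Scores are deliberately **not
clipped**: a method can score above 1 (better than the positive control's
proxy for the optimum) or arbitrarily below 0 (worse than random — easy to
achieve with, say, a negative R²). If both controls produce the same value
the anchors are degenerate and the normalized score is recorded as missing
rather than 0/0.

A method's **overall score** on a dataset is the arithmetic mean of its
non-missing normalized metric scores; ranks use competition ranking
(1, 2, 2, 4), with all-missing methods ranked last rather than dropped.
Where a task has subtasks, `collate_subtasks()` takes the unweighted mean
of per-subtask overall scores over the subtasks where the method ran —
subtasks are not weighted by dataset count, so a subtask with many
datasets does not dominate the collation.

Task **maturity** follows fixed component-count thresholds: at least one
dataset, three methods and one metric makes a *stub*; at least two
datasets, six methods and one metric makes a *full* task; anything less is
*under discussion*. Control methods count toward the tally — the
alternative (excluding them) would make the two obligatory controls
invisible to the maturity signal even though they are runnable methods.

## The synthetic study conditions

Every input is generated, with the statistical structure each task's
evaluation assumes. `synthetic_config()` fixes the default conditions:
2,000 cells, 500 genes, 4 cell types, gamma–Poisson (negative binomial,
size 10) counts over log-normal baseline gene means, 10% of genes
differentially expressed per type with log-normal fold-change scale 1,
gamma-distributed per-cell library sizes (shape 10) around 5,000 counts,
and multiplicative per-(batch, gene) log-normal batch factors of log-sd 1.
These values were chosen once as a realistic desk-scale caricature of a
moderately deep droplet experiment over a targeted gene panel.

Departures from the global defaults, and why:

* **Denoising** uses `library_size_mean = 0.5 * n_genes` (about 0.5 UMIs
  per gene, roughly 70% zeros). Denoising is motivated by sparsity; with a
  compact panel, a 5,000-count library would mean 12–33 UMIs per gene — a
  depth at which held-out-molecule evaluation makes the identity mapping
  nearly optimal and the task degenerate. Matching per-gene depth, not
  per-cell totals, preserves the evaluation's geometry.
* **Cell–cell communication** uses 5 cell types, because the
  source–target key space must contain at least 20 rankable keys for the
  top-5% odds-ratio metric to have a non-trivial top bin (4 types give
  only 16 ordered type pairs).
* Dataset functions honour the `test_mode` flag by shrinking to at most
  500 cells, so the whole roster runs in minutes on one CPU; full-mode
  sizes (1,000–2,000 cells) are stated in each task constructor.

What the generators deliberately do **not** emulate: ambient RNA, doublets,
gene–gene correlation beyond the type structure, zero inflation beyond the
negative binomial, and any real biology behind the planted ligand–receptor
truth. Passing tests therefore demonstrate that the framework's plumbing,
normalization and metrics behave as specified and that each method recovers
planted structure under its task's assumptions — not that any method would
win on real tissue.

## Task-specific modelling choices

**Label projection.** Two split modes are registered as distinct dataset
variants: a stratified random query (25% per label) and hold-one-batch-out.
The logistic regression is ridge-penalized multinomial at a fixed penalty
(`lambda = 1/n_reference`, the C = 1 convention) — no hyperparameter
search, since decentralised tuning is exactly what inflates benchmark
scores. Query-only labels never crash a method; they count as errors for
accuracy and zero-recall labels for macro-F1.

**Denoising.** Molecular cross-validation splits each observed count
binomially with `p_train = 0.9` — large enough to preserve train signal,
leaving a usable test sample. Denoised output is rescaled by
`(1 - p)/p` before comparison (expectation matching of binomial thinning).
The positive control predicts the test layer itself, rescaled — the best
attainable predictor given the split, which anchors normalization.
The Poisson loss adds ε = 1e-6 inside the log so zero predictions are
admissible. A property worth knowing: on the log-10k MSE, smooth
mean-estimates (k-NN smoothing, low-rank reconstruction) can lose to the
spiky identity because the log transform penalizes predicting the mean of
a sparse count distribution (Jensen's inequality); the same methods win
clearly on the Poisson loss, the proper scoring rule for count means. The
end-to-end expectations in the test suite are therefore phrased on the
Poisson loss.

**Dimensionality reduction.** The harness computes the log-10k layer once
and hands the same matrix to methods and metrics, so a method cannot gain
by matching the metric's normalization. The positive control passes the
full log-10k matrix to the metrics — an explicit exemption from the 2D
contract available only to control-role methods, giving the
optimal-information bound. Trustworthiness uses the standard rank-penalty
formula at k = 15; the Spearman distance correlation subsamples to at most
1,000 cells with a fixed internal seed so the metric stays a pure function
of its input.

**Batch integration.** Methods may output a corrected matrix, an
embedding, or a neighbourhood graph; converters move any output down the
chain (matrix → top-30 PCs → symmetrized binary 15-NN graph) so one metric
pair serves all three subtasks. The positive control embeds the one-hot
cell-type indicator plus N(0, 0.01²) jitter — batch-free and label-perfect
by construction; an idealization, since no real integrator sees the
labels. Mixing is the neighbour batch-composition entropy normalized by
log(n_batches); bio-conservation is the cell-type silhouette rescaled to
[0, 1] by (s + 1)/2, with singleton clusters contributing width 0.

**Spatial decomposition.** Spots are Dirichlet(1) mixtures of reference
cells with Poisson(20) cells per spot. NNLS solves each spot's CPM profile
against per-type mean CPM signatures and renormalizes to a row sum of 1;
an all-zero solution falls back to a uniform row with a warning. R² is
computed jointly over all matrix entries about the global truth mean — a
single number with no undefined per-type variance cases. A reference-free
(de novo) method slot is deliberately left unimplemented: without a
reference, inferred factors have no canonical type identity, and the
column-matching ambiguity is out of scope.

**Matching modalities.** A stub task by design. The FOSCTTM metric uses a
strict "closer than" comparison (ties favour the method) and the (n − 1)
denominator excluding the true match, so it reaches exactly 0 when
perfect and exactly 1 in the fully adversarial two-point case. Methods
never see the pairing; it lives in the truth store and is read only by the
metric and the controls.

**Cell–cell communication.** The magnitude scorer is the mean of the
ligand's average log-10k expression in the source type and the receptor's
in the target type, gated to 0 unless both genes are detected in at least
10% of their type's cells. The specificity scorer permutes labels 100
times and reports 1 − (r + 1)/(n_perm + 1) with r the count of null
scores ≥ observed (add-one correction, so a triple above every
permutation scores 100/101, never 1). Mean and max aggregation to the
subtask's key level give two subtasks × two scorers = four methods. The
positive control ranks the planted truth first (random within groups); the
negative control ranks all keys randomly. The odds ratio at the top 5%
uses a ceiling bin and the Haldane–Anscombe +0.5 correction on all four
cells whenever any cell is zero, keeping it finite.

## Numerical and engineering choices

* All-zero cells normalize to all-zero rows rather than erroring, so
  degenerate synthetic inputs flow through pipelines.
* Counts are stored sparse when density < 50%, dense otherwise — purely a
  storage contract, never observable through values.
* k-NN ties and rank ties: neighbour ranks use first-occurrence
  tie-breaking; k-NN classification breaks vote ties by smallest label
  index; ranking ties share the smaller (competition) rank; aggregation
  ties order keys lexicographically so rankings are deterministic.
* A disconnected spectral-embedding graph doubles k until connected, with
  a warning.
* Every generator and the runner are pure functions of `(parameters,
  seed)`; the runner derives per-method child seeds from a stream disjoint
  from the generators' streams.
* Resource accounting records wall-clock time and a gc-based
  approximation of peak memory per (dataset, method); it is reported in
  exports but never enters any score.
* h5ad files follow the anndata on-disk layout (X, layers/, obs, var,
  obsm/, obsp/, uns/) and are readable by the Python anndata package; the
  Matrix Market directory dialect stores genes as rows (10x convention)
  with headered CSV metadata and tagged-JSON truth stores.

## Known limitations

* Baseline anchors are only as good as the controls; a weak positive
  control lets methods exceed 1, which is permitted but complicates
  cross-metric comparability.
* The planted ligand–receptor truth preserves the evaluation geometry
  (two truth levels, ranking metrics) but none of the biology of spatial
  colocalization or cytokine signalling.
* The batch-integration positive control is label-derived and so
  simultaneously maximizes mixing and conservation on stratified synthetic
  data; real integrators face a trade-off the controls do not expose.
* Method rosters are small, self-contained analogues (no published
  denoisers or integrators); the framework, not the methods, is the
  deliverable.

## A minimal run

```{r example, eval = FALSE}
task <- task_label_projection()
classify_maturity(task)
scores <- benchmark_task(task, test_mode = TRUE, seed = 1)
scores$overall
tidy(scores)
autoplot(scores)
export_results(scores, task, "results.json")
```
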