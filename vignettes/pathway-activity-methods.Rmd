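---
title: "Methods: pathway activity inference by directed random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway activity inference by directed random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the choices that were genuinely open when it was built, and what its
validation does and does not demonstrate.

## The model

The pipeline turns a genes × samples expression matrix, a set of class
labels, a pathway collection and a directed gene-interaction graph into a
per-sample vector of pathway activities and a classifier over them.

**Normalization.** Each gene row is z-scored across all samples of a
dataset, using the sample (n − 1) standard deviation. The n − 1 choice is
the convention of expression analysis; under any per-gene affine map the
downstream F statistic is unchanged, so the choice only fixes the scale of
the z values entering the activity score. Zero-variance rows become
all-zero z rows (they then carry F = 0, p = 1 and no weight — the
least-surprise convention for a quantity that is genuinely undefined).

**Gene scoring.** The default per-gene statistic is the one-way ANOVA
F = MSB / MSW with (k − 1, N − k) degrees of freedom, the standard
multiclass extension of the two-sample t. Two alternatives share the same
table contract: Welch's heteroscedastic one-way F (with
Welch–Satterthwaite denominator degrees of freedom), preferable when class
variances differ; and the signed pooled-variance t for exactly two
classes, which reproduces the behaviour of the two-class predecessor
method (`drw_compat` mode). Degenerate genes — no variance within or
between classes — get statistic 0 and p = 1 rather than NaN; a gene with
between-class spread but exactly zero within-class variance gets the
largest finite F and p = 0, keeping the min–max weighting finite. Both
cases are flagged, and neither occurs with continuous data in practice.

**Initial weights.** Gene evidence enters the graph as
(|F| − min|F|) / (max|F| − min|F|), the extrema taken over graph nodes
with expression data; nodes without data get weight 0, and if all
statistics are equal the surviving nodes share uniform weight. The vector
is L1-normalized into a restart distribution. Min–max scaling (rather
than, say, −log p) keeps the weighting monotone in |F| and bounded, so no
single gene can dominate the restart mass before diffusion.

**The walk.** The directed graph becomes a binary adjacency matrix
augmented with one *virtual ground node*: every dangling gene (out-degree
zero) is wired to ground, and ground is wired uniformly back to every real
node. After row normalization every row is stochastic, so the walk
`W[t+1] = (1 − r) Mᵀ W[t] + r W0` conserves mass exactly. A single ground
node is the smallest construction that achieves this; it perturbs
non-dangling dynamics only through the mass that actually reaches ground.
`W0` serves as both the restart distribution and the starting state, the
standard random-walk-with-restart setup. The iteration is a contraction
with factor (1 − r) in L1, so it converges geometrically from any start;
with the default tolerance 1e-10 and r = 0.7 it terminates in a few dozen
iterations, and the cap of 10 000 iterations is never approached at
r > 0.01. After convergence the ground entry is dropped and the vector
re-normalized over real nodes. The restart probability defaults to
r = 0.7; the acceptance checks verify that classification performance is
insensitive to r across 0.3–0.9, so the default is not load-bearing.

**Pathway activity.** For pathway P with contributing genes g₁…gₙ —
members with raw p < α (default 0.05) present in both the dataset and the
graph —

> a(s) = Σᵢ w∞(gᵢ) · sgn(F(gᵢ)) · z(gᵢ, s) / √(Σᵢ w∞(gᵢ)²)

per sample s. The score is invariant under positive rescaling of the
whole weight vector. With the (nonnegative) ANOVA or Welch statistic the
sign term is identically +1 — it is retained because it becomes active in
`drw_compat` mode, where the signed t statistic lets up- and
down-regulated genes pull in opposite directions. `sgn(0)` is defined as
+1; this affects only exactly-zero statistics. The raw-p filter performs
no multiplicity correction by design: it is a per-pathway member screen,
not an inference, and correcting it would couple pathway composition to
the gene-universe size. Pathways with no contributing genes (or none with
positive diffused weight) are dropped — typically a substantial minority
of a curated collection survives in part only.

**Selection and reproducibility.** Pathway activity rows are scored with
the same ANOVA F against the training classes, ranked by |F| descending
(ties broken lexicographically by pathway ID so ranking is total and
deterministic), and the top N = 100 are selected as features. Ranking by
*training* F is the only label-safe reading: selection must not touch
test data. The cross-dataset diagnostic
`Cscore = (1/N) Σ F(train) · F(test)` over the selected pathways is
reported when a test dataset exists; selected pathways without a test
statistic are skipped and N reduced, rather than imputing a value.

**Classification.** Selected activities feed one of three standard
learners: multinomial logistic regression (`nnet::multinom`), an RBF SVM
(`e1071::svm`, decision values mapped to class probabilities by the
Platt-style fit built into libsvm), or naive Bayes (`e1071::naiveBayes`).
All are treated as interchangeable probability producers behind one
interface. Multiclass performance is the unweighted macro average of
one-vs-rest AUCs computed from each class's probability column with the
midrank tie convention; for two classes this is the ordinary AUC. The
macro-OVR extension is the most common convention where a single AUC is
reported for 3–4 class data. Note the SVM probability calibration uses an
internal cross-validation whose RNG is not under R's seed; byte-exact
reproducibility is guaranteed for the default logistic-regression and the
naive-Bayes classifiers.

**Cross-validation protocol.** Within a dataset: stratified k-fold
(default k = 10, per-class round-robin after shuffling, so per-fold class
counts deviate from proportionality by at most one sample), repeated
(default 10 times) with seeds derived deterministically from the run
seed, and averaged. z-normalization is computed once on the whole matrix —
it is unsupervised and the F statistic is invariant to it, so no label
information leaks — while everything label-dependent (gene statistics,
weights, walk, pathway selection, classifier) is refit inside each
training fold; the held-out fold is projected using training-derived
statistics, weights and gene lists only. Descriptions of hold-out
arithmetic in the pathway-classification literature are sometimes
ambiguous about an extra validation split; this package implements the
standard 9-train/1-test stratified fold, with any tuning confined to
training folds. A `transductive = TRUE` switch instead computes
statistics, weights and selection once on the entire dataset and
cross-validates only the classifier — this mimics the whole-dataset
weighting some published pipelines appear to use and is provided for
comparison, not endorsement: it leaks test labels into feature
construction. Between datasets: gene universes are intersected, each
dataset is z-normalized separately (no cross-dataset pooling), the model
is fit entirely on the training dataset and the test dataset contributes
only its z values.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure of a multiclass
expression study: i.i.d. Gaussian baseline noise; a pathway collection of
random gene subsets; a chosen subset of *informative* pathways whose
member genes receive one class-specific additive mean-shift pattern per
pathway (distinct per-class levels spread over ±δ, default δ = 2 noise
standard deviations); and a sparse random directed graph over the whole
gene universe (mean out-degree 3) in which every planted gene is
guaranteed at least one edge, so diffusion can reach it. Signal is planted
at the pathway level because that is the structure the activity score is
built to detect — recovery of the planted set is then a fair test of the
whole pipeline, not of the generator. The dataset structure (genes,
pathways, planting, graph) is a pure function of the config seed, while
expression noise can be redrawn with a separate `noise_seed`, which is how
train/test pairs sharing their underlying biology are produced.

The standard validation fixture uses the generator defaults — 5 classes ×
40 samples, 2000 genes, 200 pathways of 10–40 genes with 20 planted,
δ = 2 — and `sim_config_subtypes()` provides a 4-class unbalanced variant
(62/25/15/37 samples, 300 pathways, 4000 genes) echoing the shape of a
typical breast-cancer subtype cohort.

What the generator does *not* emulate: probe-level artefacts, batch
effects, correlated background expression, realistic (scale-free,
motif-rich) network topology, or overlap structure between curated
pathways. Passing the validation suite therefore demonstrates that the
machinery is correct and recovers pathway-level mean-shift signal under
clean conditions; it does not certify performance on real microarray
cohorts, where effect sizes are smaller and the noise is structured.

## Numerical choices and degenerate inputs

* Walk: tol = 1e-10 (L1), max_iter = 10 000, convergence by successive
  L1 change; the fixed-point residual is attached to the result.
* Degenerate statistics: see above; the same conventions apply when the
  activity rows themselves are ranked.
* Empty structures fail loudly: an all-missing expression matrix, an
  empty graph, a pathway collection with no surviving pathway, or a
  zero-weight gene list each raise an error rather than returning a
  silently empty object.
* Ties: ranking ties break lexicographically by pathway ID; AUC ties use
  midranks.
* All weight vectors are validated to be nonnegative and L1-normalized
  within 1e-8.

## Validation problem sizes

The test suite and the acceptance script run entirely on generated data:
walks are checked against a dense linear solve on 50-node graphs (20
replicates); statistics against `stats::oneway.test` / `stats::t.test`
on 100-gene matrices; the null p-value rate on 2000 genes; recovery,
cross-validated AUC, the label-permuted control and the restart-
probability sweep on the standard 2000-gene/200-sample fixture. These
sizes make the full suite run in well under a minute while leaving every
statistical check comfortably powered; the pipeline itself handles the
4000-gene subtype-shaped configuration in a few seconds per fit.

## Known limitations

* Gene IDs are opaque strings; no identifier mapping or aliasing is
  attempted.
* Genes present in the graph but absent from the expression data are
  retained with weight 0 rather than removed; their only effect is to
  absorb and re-emit walk mass.
* Edge semantics (activation vs. inhibition) are ignored: an edge is an
  edge.
* Missing expression values are rejected, not imputed.
* The p < α member screen uses raw p-values by design (see above).
* SVM probability outputs are not byte-reproducible across runs (libsvm
  internal RNG); use logistic regression or naive Bayes where exact
  reproducibility matters.
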