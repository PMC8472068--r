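# pathwalk

Pathway-level classification of multiclass gene-expression data using a
directed random walk over a gene-interaction network.

## The problem

Classifying samples (for example, tumour subtypes) directly from thousands
of individual gene-expression values is noisy and hard to interpret.
Pathway-based analysis condenses the expression profile into a few hundred
per-sample *pathway activity* scores, each summarizing a curated gene set —
but a good summary must know which member genes carry discriminative
signal, and how important each gene is in the interaction network that the
pathway lives in. `pathwalk` addresses both: genes are scored by how
strongly they separate the sample classes, that evidence is diffused over a
directed gene-interaction graph so topologically central genes gain weight,
and each pathway's significant members are folded into one activity value
per sample. The most discriminative pathways then feed a standard
classifier.

## The method

Given an expression matrix (genes × samples, Entrez-keyed), class labels,
pathway membership (GMT) and a directed gene graph:

1. **Pre-processing** — rows with missing gene IDs are dropped, repeated
   IDs averaged sample-wise, and each gene is z-scored across samples:
   *z(g) = (x − x̄) / s* with the sample (n − 1) standard deviation.
2. **Gene scoring** — a one-way ANOVA F statistic per gene,
   *F = MSB / MSW* with (k − 1, N − k) degrees of freedom, contrasts the
   k classes (Welch's heteroscedastic F and the signed pooled-variance t
   are available as alternatives).
3. **Weight diffusion** — initial weights
   *W₀ ∝ (|F| − min|F|) / (max|F| − min|F|)* are propagated by a random
   walk with restart, *Wₜ₊₁ = (1 − r) Mᵀ Wₜ + r W₀* with restart
   probability r = 0.7, where M is the row-normalized adjacency matrix
   augmented with a virtual ground node so that dangling genes keep the
   matrix row-stochastic. The walk runs to its fixed point W∞.
4. **Pathway activity** — for each pathway, members with raw p < 0.05
   that sit in both the data and the graph contribute
   *a(s) = Σᵢ w∞(gᵢ) · sgn(F(gᵢ)) · z(gᵢ, s) / √(Σᵢ w∞(gᵢ)²)*.
5. **Pathway selection** — pathways are ranked by the |F| of their
   activity rows against the training classes; the top 100 become
   classifier features. The *reproducibility power*
   *Cscore = (1/N) Σ F(train) · F(test)* of the selected set is reported
   as a cross-dataset diagnostic.
6. **Evaluation** — logistic regression, SVM or naive Bayes on the
   selected activities, under stratified 10-fold cross-validation (or
   train/test across two datasets), scored by macro one-vs-rest AUC.

A deterministic synthetic-data generator plants class-specific mean shifts
on the member genes of chosen pathways, so the whole pipeline can be
validated end to end — signal recovery, null behaviour, determinism —
without any external download.

## Worked example

```r
library(pathwalk)

cfg <- sim_config(n_genes = 500, n_per_class = rep(15, 3), n_pathways = 60,
                  pathway_size = c(8, 20), n_informative = 6, seed = 7)
sim <- simulate_dataset(cfg)
sim$expr
#> expression_matrix: 500 genes x 45 samples (raw)

Z <- zscore_normalize(sim$expr)
model <- pw_fit(Z, sim$classes, sim$pathways, sim$graph,
                pw_config(top_n = 25))
head(model$ranking$table)
#>   pathway_id statistic rank selected
#> 1     PW0009 1791.4535    1     TRUE
#> 2     PW0011 1117.0084    2     TRUE
#> 3     PW0059 1018.5438    3     TRUE
#> 4     PW0048  725.9308    4     TRUE
#> 5     PW0058  725.8672    5     TRUE
#> 6     PW0023  650.8194    6     TRUE

sum(sim$informative %in% model$ranking$selected)
#> [1] 6    # all 6 planted pathways sit inside the selected set

ev <- cv_within(sim$expr, sim$classes, sim$pathways, sim$graph,
                pw_config(top_n = 25, folds = 5, repeats = 3, seed = 11))
ev
#> pw_eval (within, logistic_regression): mean macro-OVR AUC = 1.0000
```

The ranking statistic is the ANOVA F of each pathway's activity row across
the three classes — the six planted pathways dominate it — and the
cross-validated macro one-vs-rest AUC of 1.0 reflects the strong planted
separation (class shifts of two noise standard deviations).

Files on disk work the same way through `pw_run()`, or from a shell via
the thin CLI wrapper:

```sh
Rscript inst/cli/pathwalk.R simulate --out data/
Rscript inst/cli/pathwalk.R run --expression data/expression.tsv \
    --labels data/labels.tsv --pathways data/pathways.gmt \
    --graph data/graph.tsv --out results/
```

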