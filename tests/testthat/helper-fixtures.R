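# Shared fixtures, all built in code. Heavier objects are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small 3-class dataset with 5 planted pathways; fast enough for
# per-module tests
small_sim <- function() cached("small_sim", simulate_dataset(
  sim_config(n_genes = 300L, n_per_class = rep(12L, 3),
             n_pathways = 40L, pathway_size = c(5L, 15L),
             n_informative = 5L, effect_size = 2, seed = 42L)))

# the package's standard validation fixture (generator defaults)
default_sim <- function() cached("default_sim",
                                 simulate_dataset(sim_config(seed = 101L)))

# random sparse directed graph over n nodes with ~m edges
random_graph <- function(n, m, seed) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  src <- sample(ids, m, replace = TRUE)
  dst <- sample(ids, m, replace = TRUE)
  keep <- src != dst
  suppressMessages(gene_graph(unique(cbind(src[keep], dst[keep])),
                              nodes = ids))
}

# direct linear-solve fixed point of the restart walk, ground included,
# then reduced over real nodes exactly as the iterative routine does
rwr_direct <- function(transition, w0, r) {
  n <- length(transition$nodes)
  Mt <- as.matrix(Matrix::t(transition$M))
  w <- solve(diag(n + 1) - (1 - r) * Mt, r * c(as.numeric(w0), 0))
  w <- w[seq_len(n)]
  setNames(w / sum(w), transition$nodes)
}

# random restart distribution over the graph's nodes
random_w0 <- function(transition, seed) {
  set.seed(seed)
  w <- stats::runif(length(transition$nodes))
  setNames(w / sum(w), transition$nodes)
}

# normalized matrix + classes from plain per-class value lists (one gene)
one_gene_dataset <- function(groups) {
  vals <- matrix(unlist(groups), nrow = 1)
  ids <- paste0("s", seq_along(vals))
  expr <- expression_matrix(vals, "g1", ids)
  cls <- sample_classes(rep(paste0("c", seq_along(groups)),
                            lengths(groups)), sample_ids = ids)
  list(Z = suppressMessages(zscore_normalize(expr)), classes = cls)
}

# per-gene reference statistics via stats::oneway.test / t.test
ref_stats <- function(Z, cls, kind = c("anova", "welch", "ttest")) {
  kind <- match.arg(kind)
  cls <- factor(as.character(cls[Z$sample_ids]))
  t(vapply(seq_along(Z$gene_ids), function(i) {
    y <- Z$values[i, ]
    if (kind == "ttest") {
      ht <- stats::t.test(y[cls == levels(cls)[1]],
                          y[cls == levels(cls)[2]], var.equal = TRUE)
    } else {
      ht <- stats::oneway.test(y ~ cls, var.equal = (kind == "anova"))
    }
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2)))
}
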