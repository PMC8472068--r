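# Deterministic generator of multiclass expression datasets with planted
# pathway-level signal. Baseline expression is i.i.d. Gaussian noise; each
# informative pathway carries one class-specific mean-shift pattern on all
# of its member genes, so the signal lives exactly at the level the
# activity score is built to detect. A sparse random directed graph spans
# the whole gene universe, with every informative gene guaranteed at least
# one edge so diffusion can reach it.

#' Simulation configuration
#'
#' Defaults describe the package's standard validation fixture: 5 classes
#' of 40 samples, 2000 genes, 200 pathways of 10-40 genes of which 20 are
#' informative, class shifts of 2 noise standard deviations, and a sparse
#' directed graph with 3 out-edges per gene on average.
#'
#' @param n_genes number of genes.
#' @param n_per_class integer vector of per-class sample counts.
#' @param n_pathways number of pathways.
#' @param pathway_size length-2 integer range of pathway sizes.
#' @param n_informative number of pathways carrying planted signal.
#' @param effect_size class-mean shift magnitude, in units of `noise_sd`.
#' @param noise_sd baseline expression standard deviation.
#' @param edges_per_node mean out-degree of the random directed graph.
#' @param class_labels optional class names (defaults `class1`, ...).
#' @param seed integer seed; the whole dataset is a pure function of the
#'   config including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_per_class = rep(40L, 5),
                       n_pathways = 200L, pathway_size = c(10L, 40L),
                       n_informative = 20L, effect_size = 2,
                       noise_sd = 1, edges_per_node = 3,
                       class_labels = NULL, seed = 1L) {
  stopifnot(n_genes >= 2, all(n_per_class >= 2), length(n_per_class) >= 2,
            n_pathways >= 1, length(pathway_size) == 2,
            pathway_size[1] >= 1, pathway_size[2] >= pathway_size[1],
            n_informative >= 0, n_informative <= n_pathways,
            effect_size >= 0, noise_sd > 0, edges_per_node > 0)
  if (pathway_size[2] > n_genes)
    stop("pathway size range exceeds the number of genes")
  if (is.null(class_labels))
    class_labels <- paste0("class", seq_along(n_per_class))
  stopifnot(length(class_labels) == length(n_per_class))
  structure(list(n_genes = as.integer(n_genes),
                 n_per_class = as.integer(n_per_class),
                 n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 edges_per_node = edges_per_node,
                 class_labels = as.character(class_labels),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Configuration shaped like a four-subtype breast-cancer cohort
#'
#' Mirrors the scale of a typical multiclass microarray study of breast
#' cancer subtypes: 4 unbalanced classes of 62/25/15/37 samples
#' (luminal/basal/ERBB2-enriched/normal-like), 300 pathways, and a graph
#' universe of 4000 genes.
#'
#' @param seed integer seed.
#' @param effect_size planted class-shift magnitude, default 2.
#' @return A `sim_config`.
#' @export
sim_config_subtypes <- function(seed = 1L, effect_size = 2) {
  sim_config(n_genes = 4000L, n_per_class = c(62L, 25L, 15L, 37L),
             n_pathways = 300L, pathway_size = c(10L, 60L),
             n_informative = 30L, effect_size = effect_size,
             class_labels = c("luminal", "basal", "erbb2", "normal"),
             seed = seed)
}

#' Generate a synthetic dataset with planted pathway signal
#'
#' The dataset structure — gene universe, pathway membership, the planted
#' pathway set with its per-class shift patterns, and the directed graph —
#' is a pure function of `config$seed`. The expression noise is drawn from
#' `noise_seed` (defaulting to the same seed), so two calls with one
#' config and two noise seeds yield an independent training/test pair that
#' shares its underlying biology.
#'
#' @param config a [sim_config()].
#' @param noise_seed seed for the expression noise; default `config$seed`.
#' @return A list with elements `expr` (raw [expression_matrix()]),
#'   `classes` ([sample_classes()]), `pathways` ([pathway_set()]),
#'   `graph` ([gene_graph()]) and `informative` (character vector of
#'   planted pathway IDs).
#' @export
simulate_dataset <- function(config, noise_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- as.character(sample(10000:999999, config$n_genes))
  n_samples <- sum(config$n_per_class)
  samples <- sprintf("S%04d", seq_len(n_samples))
  labels <- rep(config$class_labels, config$n_per_class)
  classes <- sample_classes(labels, sample_ids = samples,
                            class_order = config$class_labels)
  k <- length(config$class_labels)

  pw_ids <- sprintf("PW%04d", seq_len(config$n_pathways))
  sizes <- sample(config$pathway_size[1]:config$pathway_size[2],
                  config$n_pathways, replace = TRUE)
  members <- lapply(sizes, function(s) sample(genes, s))
  names(members) <- pw_ids
  informative <- sort(sample(pw_ids, config$n_informative))
  # one distinct shift level per class and pathway, spread over
  # [-delta, delta]
  patterns <- lapply(informative, function(pid)
    config$effect_size * sample(seq(-1, 1, length.out = k)))
  names(patterns) <- informative

  n_edges <- round(config$edges_per_node * config$n_genes)
  src <- sample(genes, n_edges, replace = TRUE)
  dst <- sample(genes, n_edges, replace = TRUE)
  keep <- src != dst
  edges <- unique(cbind(src[keep], dst[keep]))
  # guarantee diffusion can reach every planted gene
  inf_genes <- unique(unlist(members[informative]))
  touched <- inf_genes %in% c(edges[, 1], edges[, 2])
  if (any(!touched)) {
    extra_to <- vapply(inf_genes[!touched], function(g)
      sample(setdiff(genes, g), 1), "")
    edges <- unique(rbind(edges, cbind(inf_genes[!touched], extra_to)))
  }
  graph <- suppressMessages(gene_graph(edges, nodes = genes))

  set.seed(noise_seed)
  vals <- matrix(rnorm(config$n_genes * n_samples, 0, config$noise_sd),
                 config$n_genes, n_samples)
  for (pid in informative) {
    rows <- match(members[[pid]], genes)
    for (c_i in seq_len(k)) {
      cols <- which(labels == config$class_labels[c_i])
      vals[rows, cols] <- vals[rows, cols] + patterns[[pid]][c_i]
    }
  }

  list(expr = expression_matrix(vals, genes, samples),
       classes = classes,
       pathways = pathway_set(members),
       graph = graph,
       informative = informative)
}

#' Write a simulated dataset to a directory
#'
#' Emits `expression.tsv`, `labels.tsv`, `pathways.gmt`, `graph.tsv` and
#' `informative.tsv` (the planted-pathway truth, one ID per line) in the
#' formats the package readers consume.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_labels(sim$classes, file.path(dir, "labels.tsv"))
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  write_edge_list(sim$graph, file.path(dir, "graph.tsv"))
  writeLines(c("pathway_id", sim$informative),
             file.path(dir, "informative.tsv"))
  invisible(dir)
}
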