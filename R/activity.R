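# Pathway activity: for each pathway, its significant member genes (raw
# p < alpha, present in both the expression data and the graph) are
# combined, per sample, into
#   a(s) = sum_i w_inf(g_i) * sgn(F(g_i)) * z_{g_i}(s) / sqrt(sum_i w_inf^2)
# With a nonnegative multiclass F the sign term is identically +1; it is
# active when the signed two-class t statistic drives the pipeline.

#' Significant member genes of one pathway
#'
#' @param pathway_genes character vector of member gene IDs (pathway order).
#' @param stats a `gene_stat_table`.
#' @param graph a [gene_graph()].
#' @param data_genes character vector of gene IDs present in the dataset.
#' @param alpha raw p-value threshold, default 0.05.
#' @return Character vector of genes with p < alpha that are in both the
#'   dataset and the graph, in pathway order. May be empty.
#' @export
contributing_genes <- function(pathway_genes, stats, graph, data_genes,
                               alpha = 0.05) {
  p <- stats$p_value[match(pathway_genes, stats$gene_id)]
  keep <- !is.na(p) & p < alpha &
    pathway_genes %in% data_genes &
    pathway_genes %in% graph$nodes
  pathway_genes[keep]
}

#' Activity of one pathway across samples
#'
#' @param genes non-empty character vector of contributing genes.
#' @param w_inf stationary weight vector (named, from
#'   [random_walk_with_restart()]).
#' @param stats a `gene_stat_table` (provides the sign of each statistic).
#' @param Z normalized [expression_matrix()] supplying the z rows.
#' @return Numeric vector of activity values, one per sample of `Z`.
#' @export
pathway_activity <- function(genes, w_inf, stats, Z) {
  if (length(genes) == 0L) stop("empty gene list")
  w <- w_inf[genes]
  if (anyNA(w)) stop("gene(s) without a diffused weight: ",
                     paste(genes[is.na(w)], collapse = ", "))
  if (all(w == 0)) stop("pathway has no diffused weight")
  sgn <- stat_sign(stats$statistic[match(genes, stats$gene_id)])
  zrows <- Z$values[match(genes, Z$gene_ids), , drop = FALSE]
  as.numeric(crossprod(w * sgn, zrows)) / sqrt(sum(w^2))
}

#' Infer the pathway-by-sample activity matrix
#'
#' Pathways whose contributing-gene list is empty (no member significant at
#' `alpha`, or none with a graph weight) are dropped; in typical runs only a
#' subset of the input pathways survives this filter.
#'
#' @param pathways a [pathway_set()].
#' @param w_inf stationary weight vector.
#' @param stats a `gene_stat_table` (training-derived when projecting a
#'   test set).
#' @param Z normalized [expression_matrix()].
#' @param alpha raw p-value threshold for member genes, default 0.05.
#' @param restrict_to optional character vector: only compute these
#'   pathways (used when projecting a test set onto training selections).
#' @param gene_lists optional named list of pre-computed contributing genes
#'   (training-derived projection); bypasses the significance filter.
#' @return Object of class `activity_matrix`: list with `values` (pathways
#'   x samples matrix, dimnames set) and `contributing` (named list of gene
#'   vectors).
#' @export
infer_activity_matrix <- function(pathways, w_inf, stats, Z, alpha = 0.05,
                                  restrict_to = NULL, gene_lists = NULL) {
  stopifnot(inherits(pathways, "pathway_set"))
  ids <- names(pathways$genes)
  if (!is.null(restrict_to)) ids <- ids[ids %in% restrict_to]
  if (is.null(gene_lists)) {
    gene_lists <- lapply(pathways$genes[ids], contributing_genes,
                         stats = stats, graph = list(nodes = names(w_inf)),
                         data_genes = Z$gene_ids, alpha = alpha)
  } else {
    gene_lists <- gene_lists[ids]
  }
  keep <- lengths(gene_lists) > 0L
  # a contributing gene can still carry zero diffused mass; such pathways
  # cannot be scored and are dropped alongside the empty ones
  keep[keep] <- vapply(gene_lists[keep], function(g)
    any(w_inf[g] > 0), TRUE)
  if (!any(keep)) stop("no pathway has significant genes with graph weight")
  ids <- ids[keep]
  gene_lists <- gene_lists[keep]
  vals <- t(vapply(ids, function(id)
    pathway_activity(gene_lists[[id]], w_inf, stats, Z),
    numeric(length(Z$sample_ids))))
  dimnames(vals) <- list(ids, Z$sample_ids)
  structure(list(values = vals, contributing = gene_lists),
            class = "activity_matrix")
}

#' Rank pathways by discriminative power and select the top N
#'
#' Each pathway's activity row is scored with the one-way ANOVA F against
#' the training classes; pathways are ranked by |F| descending (ties broken
#' by pathway ID) and the top `n` flagged as selected.
#'
#' @param act a training `activity_matrix`.
#' @param classes [sample_classes()] for the training samples.
#' @param n number of pathways to select, default 100; clamped to the
#'   number available. `Inf` selects all.
#' @return Object of class `pathway_ranking`: list with `table` (data frame
#'   `pathway_id`, `statistic`, `rank`, `selected`) and `selected`
#'   (character vector of selected IDs in rank order).
#' @export
rank_and_select <- function(act, classes, n = 100) {
  stopifnot(inherits(act, "activity_matrix"))
  cls <- align_classes(classes, colnames(act$values))
  st <- .anova_f(act$values, cls)
  ord <- order(-abs(st$statistic), rownames(act$values))
  ids <- rownames(act$values)[ord]
  n_sel <- min(n, length(ids))
  tab <- data.frame(pathway_id = ids,
                    statistic = st$statistic[ord],
                    rank = seq_along(ids),
                    selected = seq_along(ids) <= n_sel,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, selected = ids[seq_len(n_sel)]),
            class = "pathway_ranking")
}

#' Reproducibility power of the selected pathways
#'
#' Mean product of each selected pathway's discriminative F statistic in
#' the training and in the test data. Selected pathways without a test
#' statistic are skipped (the averaging count shrinks accordingly).
#'
#' @param ranking a `pathway_ranking` from the training data.
#' @param train_f named numeric: per-pathway F in training.
#' @param test_f named numeric: per-pathway F in test.
#' @return The mean cross-dataset F product (scalar).
#' @export
reproducibility_power <- function(ranking, train_f, test_f) {
  stopifnot(inherits(ranking, "pathway_ranking"))
  ids <- ranking$selected
  ids <- ids[ids %in% names(train_f) & ids %in% names(test_f)]
  ids <- ids[is.finite(train_f[ids]) & is.finite(test_f[ids])]
  if (length(ids) == 0L)
    stop("no selected pathway has statistics in both datasets")
  mean(train_f[ids] * test_f[ids])
}
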