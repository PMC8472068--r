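#' Run the full pipeline from files on disk
#'
#' Reads the expression matrix, labels, GMT pathways and edge-list graph,
#' pre-processes (drop missing gene IDs, average repeats, z-score), then
#' either cross-validates within the dataset or — when a test dataset is
#' given — trains on the first dataset and evaluates on the second.
#' Writes, under `out_dir`: `weights.tsv` (diffused gene weights of the
#' final model fit on all training data), `ranking.tsv`, `activity.tsv`,
#' and `eval.json` / `eval.tsv` with the AUC results. Repeated runs with
#' the same inputs and config produce byte-identical outputs.
#'
#' @param expression,labels,pathways,graph input file paths (see
#'   [read_expression()], [read_labels()], [read_gmt()],
#'   [read_edge_list()]).
#' @param config a [pw_config()].
#' @param test_expression,test_labels optional independent test dataset;
#'   switches to the between-datasets protocol.
#' @param out_dir output directory; created if needed. `NULL` skips
#'   writing.
#' @param id_column identifier column of the expression files.
#' @return The `pw_eval` result, invisibly when `out_dir` is set.
#' @export
pw_run <- function(expression, labels, pathways, graph,
                   config = pw_config(),
                   test_expression = NULL, test_labels = NULL,
                   out_dir = NULL, id_column = "gene_id") {
  expr <- collapse_gene_ids(read_expression(expression, id_column))
  cls <- read_labels(labels)
  ps <- read_gmt(pathways)
  g <- read_edge_list(graph)
  between <- !is.null(test_expression)
  if (between) {
    if (is.null(test_labels))
      stop("test_labels required with test_expression")
    expr2 <- collapse_gene_ids(read_expression(test_expression, id_column))
    cls2 <- read_labels(test_labels)
    res <- eval_between(expr, cls, expr2, cls2, ps, g, config)
    final <- res$model
  } else {
    res <- cv_within(expr, cls, ps, g, config)
    final <- pw_fit(zscore_normalize(expr), cls, ps, g, config)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_weights(final$w_inf, file.path(out_dir, "weights.tsv"))
    write_ranking(final$ranking, file.path(out_dir, "ranking.tsv"))
    write_activity(final$activity, file.path(out_dir, "activity.tsv"))
    write_eval(res, out_dir)
    return(invisible(res))
  }
  res
}

# eval report: flat TSV plus a JSON mirror
write_eval <- function(res, out_dir) {
  fields <- list(protocol = res$protocol, classifier = res$classifier,
                 mean_auc = res$mean_auc, seed = res$seed)
  if (!is.null(res$cscore)) fields$cscore <- res$cscore
  if (res$protocol == "within") {
    fields$folds <- res$folds
    fields$repeats <- res$repeats
    fields$fold_auc <- as.numeric(t(res$auc))
  }
  jsonlite::write_json(fields, file.path(out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  tsv <- data.frame(metric = c("protocol", "classifier", "mean_auc"),
                    value = c(res$protocol, res$classifier,
                              sprintf("%.17g", res$mean_auc)))
  write.table(tsv, file.path(out_dir, "eval.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
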