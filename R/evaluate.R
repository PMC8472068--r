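#' Pipeline configuration
#'
#' Collects every tunable of the pathway-walk pipeline with its default.
#'
#' @param stat per-gene statistic: `"anova"` (default), `"welch"`, `"ttest"`.
#' @param r restart probability of the walk, default 0.7.
#' @param tol walk convergence tolerance (L1), default 1e-10.
#' @param max_iter walk iteration cap, default 10000.
#' @param alpha raw p-value threshold for pathway member genes, default 0.05.
#' @param top_n number of pathways selected as classifier features,
#'   default 100.
#' @param classifier `"logistic_regression"` (default), `"svm"` or
#'   `"naive_bayes"`.
#' @param folds cross-validation folds, default 10.
#' @param repeats cross-validation repeats (averaged), default 10.
#' @param seed integer seed controlling fold assignment.
#' @param transductive if `TRUE`, gene statistics, weights and the pathway
#'   selection are computed once on the whole dataset before
#'   cross-validation (test-fold labels then leak into feature
#'   construction); default `FALSE` recomputes them inside each fold.
#' @param drw_compat if `TRUE`, run the two-class baseline configuration:
#'   signed pooled-variance t statistic and no pathway selection
#'   (`top_n = Inf`).
#' @return A list of class `pw_config`.
#' @export
pw_config <- function(stat = c("anova", "welch", "ttest"),
                      r = 0.7, tol = 1e-10, max_iter = 10000L,
                      alpha = 0.05, top_n = 100,
                      classifier = c("logistic_regression", "svm",
                                     "naive_bayes"),
                      folds = 10L, repeats = 10L, seed = 1L,
                      transductive = FALSE, drw_compat = FALSE) {
  stat <- match.arg(stat)
  classifier <- match.arg(classifier)
  if (drw_compat) {
    stat <- "ttest"
    top_n <- Inf
  }
  stopifnot(r > 0, r <= 1, tol > 0, alpha > 0, alpha <= 1,
            top_n >= 1, folds >= 2, repeats >= 1)
  structure(list(stat = stat, r = r, tol = tol,
                 max_iter = as.integer(max_iter), alpha = alpha,
                 top_n = top_n, classifier = classifier,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 transductive = isTRUE(transductive),
                 drw_compat = isTRUE(drw_compat)),
            class = "pw_config")
}

#' Fit the full pathway-walk model on training data
#'
#' Runs statistic -> initial weights -> random walk -> activity inference
#' -> pathway ranking/selection -> classifier fit, all from the training
#' samples only.
#'
#' @param Z normalized [expression_matrix()] (training samples).
#' @param classes [sample_classes()] covering the training samples.
#' @param pathways a [pathway_set()].
#' @param graph a [gene_graph()].
#' @param config a [pw_config()].
#' @param transition optional pre-built [build_transition()] result (the
#'   transition matrix depends only on the graph, so callers looping over
#'   folds pass it in once).
#' @return Object of class `pw_model` holding the gene statistics, the
#'   diffused weights, the training activity matrix, the pathway ranking
#'   and the fitted classifier.
#' @export
pw_fit <- function(Z, classes, pathways, graph, config = pw_config(),
                   transition = NULL) {
  stopifnot(inherits(config, "pw_config"))
  if (is.null(transition)) transition <- build_transition(graph)
  stats <- gene_stats(Z, classes, stat = config$stat)
  w0 <- initial_weights(stats, graph)
  w_inf <- random_walk_with_restart(transition, w0, r = config$r,
                                    tol = config$tol,
                                    max_iter = config$max_iter)
  act <- infer_activity_matrix(pathways, w_inf, stats, Z,
                               alpha = config$alpha)
  ranking <- rank_and_select(act, classes, n = config$top_n)
  sel <- ranking$selected
  x <- t(act$values[sel, , drop = FALSE])
  cls <- align_classes(classes, rownames(x))
  clf <- fit_classifier(x, cls, config$classifier)
  structure(list(stats = stats, w0 = w0, w_inf = w_inf,
                 activity = act, ranking = ranking, selected = sel,
                 classifier = clf, config = config,
                 gene_ids = Z$gene_ids),
            class = "pw_model")
}

#' Project new samples onto a fitted model's pathway activities
#'
#' Test samples contribute only their z-scores: the gene statistics, the
#' diffused weights and the per-pathway contributing-gene lists all come
#' from the training fit.
#'
#' @param model a `pw_model`.
#' @param Z_new normalized [expression_matrix()] over (at least) the
#'   training genes.
#' @return An `activity_matrix` for the selected pathways.
#' @export
project_activity <- function(model, Z_new) {
  stopifnot(inherits(model, "pw_model"))
  missing_g <- setdiff(unlist(model$activity$contributing[model$selected]),
                       Z_new$gene_ids)
  if (length(missing_g))
    stop("new data lacks training genes: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  infer_activity_matrix(
    pathway_set(model$activity$contributing[model$selected]),
    model$w_inf, model$stats, Z_new,
    gene_lists = model$activity$contributing[model$selected])
}

#' @export
predict.pw_model <- function(object, Z_new, ...) {
  act <- project_activity(object, Z_new)
  x <- t(act$values[object$selected, , drop = FALSE])
  predict_scores(object$classifier, x)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(classes, k, seed) {
  cls <- factor(as.character(classes))
  n_min <- min(table(cls))
  if (n_min < k) {
    warning("smallest class has ", n_min, " samples; reducing folds from ",
            k, " to ", n_min)
    k <- n_min
  }
  fold <- integer(length(cls))
  set.seed(seed)
  for (lv in levels(cls)) {
    idx <- which(cls == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  names(fold) <- names(classes)
  attr(fold, "k") <- k
  fold
}

# column subset of an expression matrix
subset_samples <- function(Z, keep) {
  expression_matrix(Z$values[, keep, drop = FALSE], Z$gene_ids,
                    Z$sample_ids[keep], normalized = Z$normalized)
}

#' Stratified repeated cross-validation within one dataset
#'
#' The matrix is z-normalized once (an unsupervised, per-gene affine map
#' under which the F statistic is invariant); inside each fold the whole
#' pipeline — gene statistics, weights, walk, activity, pathway selection,
#' classifier — is refit on the training folds only, and the held-out fold
#' is projected and scored. With `transductive = TRUE` in the config,
#' statistics/weights/selection are instead computed once on all samples
#' (the protocol some pathway-classification studies appear to use, at the
#' cost of label leakage) and only the classifier is cross-validated.
#'
#' @param expr an [expression_matrix()] with unique gene IDs (raw matrices
#'   are normalized internally).
#' @param classes a [sample_classes()] factor.
#' @param pathways a [pathway_set()].
#' @param graph a [gene_graph()].
#' @param config a [pw_config()].
#' @return Object of class `pw_eval`: per-repeat-per-fold AUC matrix
#'   `auc`, scalar `mean_auc`, and the run metadata.
#' @export
cv_within <- function(expr, classes, pathways, graph,
                      config = pw_config()) {
  Z <- if (expr$normalized) expr else zscore_normalize(expr)
  cls <- align_classes(classes, Z$sample_ids)
  transition <- build_transition(graph)
  full_model <- NULL
  if (config$transductive)
    full_model <- pw_fit(Z, cls, pathways, graph, config, transition)
  k <- config$folds
  n_min <- min(table(cls))
  if (n_min < k) {
    warning("smallest class has ", n_min, " samples; reducing folds from ",
            k, " to ", n_min)
    k <- n_min
  }
  auc <- matrix(NA_real_, config$repeats, k,
                dimnames = list(paste0("repeat", seq_len(config$repeats)),
                                paste0("fold", seq_len(k))))
  for (rep_i in seq_len(config$repeats)) {
    seed_i <- (config$seed + 104729L * rep_i) %% .Machine$integer.max
    fold <- stratified_folds(cls, k, seed_i)
    for (f in seq_len(k)) {
      test_idx <- fold == f
      Z_tr <- subset_samples(Z, !test_idx)
      Z_te <- subset_samples(Z, test_idx)
      if (config$transductive) {
        x_tr <- t(full_model$activity$values[full_model$selected,
                                             !test_idx, drop = FALSE])
        clf <- fit_classifier(x_tr, cls[!test_idx], config$classifier)
        x_te <- t(full_model$activity$values[full_model$selected,
                                             test_idx, drop = FALSE])
        scores <- predict_scores(clf, x_te)
      } else {
        model <- pw_fit(Z_tr, cls[!test_idx], pathways, graph, config,
                        transition)
        scores <- predict(model, Z_te)
      }
      auc[rep_i, f] <- macro_ovr_auc(scores, cls[test_idx])
    }
  }
  structure(list(auc = auc, mean_auc = mean(auc),
                 classifier = config$classifier, protocol = "within",
                 folds = ncol(auc), repeats = config$repeats,
                 seed = config$seed, config = config),
            class = "pw_eval")
}

#' Train on one dataset, evaluate on an independent one
#'
#' Gene universes are intersected; each dataset is z-normalized
#' independently; statistics, weights and the pathway selection come from
#' the training dataset alone. Classes not shared by both datasets are
#' dropped with a warning. Alongside the test AUC, the reproducibility
#' power of the selected pathways (mean train-by-test F product) is
#' reported as a diagnostic.
#'
#' @param train_expr,train_classes training dataset (unique gene IDs).
#' @param test_expr,test_classes independent test dataset.
#' @param pathways a [pathway_set()].
#' @param graph a [gene_graph()].
#' @param config a [pw_config()].
#' @return Object of class `pw_eval` with elements `auc` (scalar test
#'   AUC), `mean_auc`, `cscore`, and the fitted `model`.
#' @export
eval_between <- function(train_expr, train_classes, test_expr, test_classes,
                         pathways, graph, config = pw_config()) {
  shared_genes <- intersect(train_expr$gene_ids, test_expr$gene_ids)
  if (length(shared_genes) == 0L)
    stop("training and test datasets share no genes")
  keep_tr <- train_expr$gene_ids %in% shared_genes
  keep_te <- test_expr$gene_ids %in% shared_genes
  tr <- expression_matrix(train_expr$values[keep_tr, , drop = FALSE],
                          train_expr$gene_ids[keep_tr],
                          train_expr$sample_ids)
  te <- expression_matrix(test_expr$values[keep_te, , drop = FALSE],
                          test_expr$gene_ids[keep_te],
                          test_expr$sample_ids)
  shared_cls <- intersect(unique(as.character(train_classes)),
                          unique(as.character(test_classes)))
  if (length(shared_cls) < 2L)
    stop("training and test datasets share fewer than 2 classes")
  drop_tr <- names(train_classes)[!as.character(train_classes) %in% shared_cls]
  drop_te <- names(test_classes)[!as.character(test_classes) %in% shared_cls]
  if (length(drop_tr) || length(drop_te))
    warning("dropping ", length(drop_tr) + length(drop_te),
            " sample(s) from classes not shared by both datasets")
  tr <- subset_samples(tr, !tr$sample_ids %in% drop_tr)
  te <- subset_samples(te, !te$sample_ids %in% drop_te)
  Z_tr <- if (tr$normalized) tr else zscore_normalize(tr)
  Z_te <- if (te$normalized) te else zscore_normalize(te)
  cls_tr <- align_classes(train_classes, Z_tr$sample_ids)
  cls_te <- align_classes(test_classes, Z_te$sample_ids)
  model <- pw_fit(Z_tr, cls_tr, pathways, graph, config)
  scores <- predict(model, Z_te)
  auc <- macro_ovr_auc(scores, cls_te)
  # reproducibility diagnostic: F of each selected pathway's activity in
  # both datasets
  act_te <- project_activity(model, Z_te)
  f_te <- .anova_f(act_te$values,
                   align_classes(test_classes, colnames(act_te$values)))
  test_f <- setNames(f_te$statistic, rownames(act_te$values))
  train_f <- setNames(model$ranking$table$statistic,
                      model$ranking$table$pathway_id)
  cscore <- reproducibility_power(model$ranking, train_f, test_f)
  structure(list(auc = auc, mean_auc = auc, cscore = cscore,
                 classifier = config$classifier, protocol = "between",
                 seed = config$seed, model = model, config = config),
            class = "pw_eval")
}

#' @export
print.pw_eval <- function(x, ...) {
  cat(sprintf("pw_eval (%s, %s): mean macro-OVR AUC = %.4f\n",
              x$protocol, x$classifier, x$mean_auc))
  if (!is.null(x$cscore))
    cat(sprintf("  reproducibility power (Cscore) = %.4f\n", x$cscore))
  invisible(x)
}
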