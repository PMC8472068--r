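# Classifiers behind one interface: fit on a samples-by-features activity
# matrix, return class-probability scores with columns in class-level
# order. All three are off-the-shelf learners; SVM decision values are
# mapped to probabilities by the standard Platt-style fit built into
# e1071.

fit_classifier <- function(x, y, method = c("logistic_regression",
                                            "svm", "naive_bayes")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  feat <- colnames(x)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_along(df))
  model <- switch(method,
    logistic_regression = {
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, trace = FALSE,
                     MaxNWts = 1e6, maxit = 200)
    },
    svm = e1071::svm(x = as.matrix(df), y = y, probability = TRUE,
                     kernel = "radial"),
    naive_bayes = e1071::naiveBayes(x = df, y = y))
  structure(list(model = model, method = method, levels = levels(y),
                 features = feat),
            class = "pw_classifier")
}

# class-probability matrix, samples x levels, column order = training levels
predict_scores <- function(clf, x) {
  x <- as.matrix(x)
  if (!is.null(clf$features) && !is.null(colnames(x)))
    x <- x[, clf$features, drop = FALSE]
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_along(df))
  scores <- switch(clf$method,
    logistic_regression = {
      p <- predict(clf$model, newdata = df, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # 2-class multinom
      p
    },
    svm = {
      pr <- predict(clf$model, as.matrix(df), probability = TRUE)
      attr(pr, "probabilities")
    },
    naive_bayes = predict(clf$model, df, type = "raw"))
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)) || !all(clf$levels %in% colnames(scores)))
    colnames(scores) <- clf$levels
  scores <- scores[, clf$levels, drop = FALSE]
  rownames(scores) <- rownames(x)
  scores
}

#' Macro-averaged one-vs-rest AUC
#'
#' Computes, for every class, the AUC of that class's score column with the
#' class's samples as positives and all others as negatives (midrank
#' convention for ties), then averages unweighted over classes. For two
#' classes this reduces to the ordinary AUC.
#'
#' @param scores numeric matrix, samples x classes, columns named by class.
#' @param truth a [sample_classes()] factor (or plain factor) giving the
#'   true class per row of `scores`; every scored class must occur.
#' @return Scalar AUC in [0, 1].
#' @export
macro_ovr_auc <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- factor(as.character(truth))
  if (nrow(scores) != length(truth))
    stop("scores and truth differ in length")
  classes <- colnames(scores)
  if (is.null(classes)) stop("score columns must be named by class")
  absent <- setdiff(classes, levels(truth))
  if (length(absent))
    stop("class absent from truth: ", paste(absent, collapse = ", "))
  aucs <- vapply(classes, function(cl) {
    pos <- truth == cl
    .rank_auc(scores[, cl], pos)
  }, 0)
  mean(aucs)
}

# Mann-Whitney AUC via midranks: P(score_pos > score_neg) + 0.5 P(tie)
.rank_auc <- function(s, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both positives and negatives")
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
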