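# Per-gene multiclass differential expression. All three statistics are
# computed vectorized over the gene dimension from per-class row sums;
# looping stats::oneway.test over 10^4 genes inside cross-validation folds
# would dominate the run time.

#' Per-gene differential-expression statistics
#'
#' Computes, for every gene (row) of a normalized expression matrix, a
#' statistic contrasting the sample classes:
#' \describe{
#'   \item{`anova`}{one-way ANOVA F = MSB / MSW with (k-1, N-k) degrees of
#'     freedom; the default, valid for any number of classes.}
#'   \item{`welch`}{Welch's heteroscedastic one-way F with
#'     Welch-Satterthwaite denominator degrees of freedom.}
#'   \item{`ttest`}{pooled-variance two-sample t (signed; first class level
#'     minus second), two-sided p with N-2 df; exactly 2 classes required.}
#' }
#' Genes with no variance within or between classes are flagged degenerate
#' and assigned statistic 0, p = 1. A gene with between-class variance but
#' exactly zero within-class variance gets the largest finite F and p = 0,
#' so downstream min-max weighting stays finite.
#'
#' @param Z a normalized [expression_matrix()].
#' @param classes a [sample_classes()] factor covering `Z`'s samples;
#'   every class needs >= 2 samples.
#' @param stat statistic kind: `"anova"` (default), `"welch"` or `"ttest"`.
#' @return A data frame of class `gene_stat_table` with columns `gene_id`,
#'   `statistic`, `p_value`, `df_between`, `df_within`, `degenerate`, and
#'   attribute `statistic_kind`.
#' @export
gene_stats <- function(Z, classes, stat = c("anova", "welch", "ttest")) {
  stat <- match.arg(stat)
  stopifnot(inherits(Z, "expression_matrix"))
  if (!Z$normalized)
    stop("gene statistics expect a z-score normalized matrix")
  cls <- align_classes(classes, Z$sample_ids)
  res <- switch(stat,
    anova = .anova_f(Z$values, cls),
    welch = .welch_f(Z$values, cls),
    ttest = .pooled_t(Z$values, cls))
  res <- cbind(data.frame(gene_id = Z$gene_ids, stringsAsFactors = FALSE),
               res)
  attr(res, "statistic_kind") <-
    switch(stat, anova = "anova_f", welch = "welch_f", ttest = "t_equal_var")
  class(res) <- c("gene_stat_table", "data.frame")
  res
}

# one-way ANOVA on the rows of a plain matrix; shared with pathway ranking
.anova_f <- function(values, cls) {
  k <- nlevels(cls)
  N <- length(cls)
  n_c <- tabulate(cls)
  grand <- rowMeans(values)
  sst <- rowSums((values - grand)^2)
  ssb <- numeric(nrow(values))
  for (c_i in seq_len(k)) {
    m_c <- rowMeans(values[, cls == levels(cls)[c_i], drop = FALSE])
    ssb <- ssb + n_c[c_i] * (m_c - grand)^2
  }
  ssw <- pmax(sst - ssb, 0)
  eps <- 1e-12 * pmax(sst, 1)
  degen <- ssw <= eps & ssb <= eps
  exact <- ssw <= eps & ssb > eps
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  f[degen] <- 0; p[degen] <- 1
  f[exact] <- .Machine$double.xmax; p[exact] <- 0
  data.frame(statistic = f, p_value = p,
             df_between = k - 1L, df_within = N - k,
             degenerate = degen | exact)
}

.welch_f <- function(values, cls) {
  k <- nlevels(cls)
  n_c <- tabulate(cls)
  m <- v <- matrix(0, nrow(values), k)
  for (c_i in seq_len(k)) {
    block <- values[, cls == levels(cls)[c_i], drop = FALSE]
    m[, c_i] <- rowMeans(block)
    v[, c_i] <- rowSums((block - m[, c_i])^2) / (n_c[c_i] - 1)
  }
  degen <- apply(v, 1, function(row) any(row <= 0))
  v[v <= 0] <- NA  # masked; degenerate genes are overwritten below
  w <- sweep(1 / v, 2, n_c, `*`)
  U <- rowSums(w)
  mtilde <- rowSums(w * m) / U
  A <- rowSums(w * (m - mtilde)^2) / (k - 1)
  tmp <- sweep((1 - w / U)^2, 2, n_c - 1, `/`)
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * rowSums(tmp)
  f <- A / B
  df2 <- (k^2 - 1) / (3 * rowSums(tmp))
  p <- pf(f, k - 1, df2, lower.tail = FALSE)
  f[degen] <- 0; p[degen] <- 1; df2[degen] <- NA
  data.frame(statistic = f, p_value = p,
             df_between = k - 1L, df_within = df2, degenerate = degen)
}

.pooled_t <- function(values, cls) {
  if (nlevels(cls) != 2L)
    stop("pooled t-test requires exactly 2 classes; use stat = \"anova\" ",
         "for multiclass data")
  i1 <- cls == levels(cls)[1]
  i2 <- cls == levels(cls)[2]
  n1 <- sum(i1); n2 <- sum(i2); N <- n1 + n2
  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  ss1 <- rowSums((values[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, i2, drop = FALSE] - m2)^2)
  s2p <- (ss1 + ss2) / (N - 2)
  se <- sqrt(s2p * (1 / n1 + 1 / n2))
  eps <- 1e-12 * pmax(ss1 + ss2 + (m1 - m2)^2, 1)
  degen <- se^2 <= eps & abs(m1 - m2)^2 <= eps
  exact <- se^2 <= eps & abs(m1 - m2)^2 > eps
  t <- (m1 - m2) / se
  p <- 2 * pt(abs(t), N - 2, lower.tail = FALSE)
  t[degen] <- 0; p[degen] <- 1
  t[exact] <- sign(m1 - m2)[exact] * .Machine$double.xmax; p[exact] <- 0
  data.frame(statistic = t, p_value = p,
             df_between = 1L, df_within = N - 2L,
             degenerate = degen | exact)
}

# sign convention used by the activity score: -1 for negative statistics,
# +1 for positive and for exact zero
stat_sign <- function(x) ifelse(x < 0, -1, 1)
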