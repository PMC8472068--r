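# Pre-processing: raw matrices off a microarray export typically carry rows
# whose probe failed to map (blank Entrez ID) and several probes mapping to
# one gene (repeated ID). Rows without an ID are dropped; repeated IDs are
# averaged sample-wise. Rows are then z-scored per gene across all samples.

#' Drop missing gene IDs and average repeated ones
#'
#' Rows with a missing identifier are removed. For each repeated identifier
#' a single row is kept whose value in every sample is the arithmetic mean
#' of the repeated rows. Output order is first-occurrence order.
#'
#' @param raw a raw [expression_matrix()].
#' @return An [expression_matrix()] with unique, non-missing gene IDs.
#' @export
collapse_gene_ids <- function(raw) {
  stopifnot(inherits(raw, "expression_matrix"))
  keep <- !is.na(raw$gene_ids) & raw$gene_ids != ""
  if (!any(keep)) stop("no usable genes: all gene IDs are missing")
  ids <- raw$gene_ids[keep]
  vals <- raw$values[keep, , drop = FALSE]
  if (!anyDuplicated(ids)) {
    return(expression_matrix(vals, ids, raw$sample_ids,
                             normalized = raw$normalized))
  }
  uid <- unique(ids)
  grp <- match(ids, uid)
  # sample-wise mean per repeated ID: sum rows by group, divide by count
  sums <- rowsum(vals, grp, reorder = TRUE)
  counts <- tabulate(grp, nbins = length(uid))
  out <- sums / counts
  expression_matrix(out, uid, raw$sample_ids, normalized = raw$normalized)
}

#' Z-score normalize each gene across all samples
#'
#' Each row is transformed to (value - row mean) / row standard deviation,
#' using the sample (n - 1) denominator. Rows with zero variance are set to
#' all-zero and reported; downstream they carry a zero F statistic and no
#' weight.
#'
#' @param x an [expression_matrix()] with unique gene IDs and >= 2 samples.
#' @return The normalized [expression_matrix()] (`normalized = TRUE`).
#' @export
zscore_normalize <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (anyNA(x$gene_ids) || anyDuplicated(x$gene_ids))
    stop("collapse gene IDs before normalizing")
  n <- length(x$sample_ids)
  if (n < 2L) stop("z-score normalization needs >= 2 samples (sd undefined)")
  mu <- rowMeans(x$values)
  centred <- x$values - mu
  s <- sqrt(rowSums(centred^2) / (n - 1))
  flat <- s == 0
  if (any(flat))
    message(sum(flat), " zero-variance gene(s) set to all-zero z-scores")
  s[flat] <- 1
  z <- centred / s
  z[flat, ] <- 0
  expression_matrix(z, x$gene_ids, x$sample_ids, normalized = TRUE)
}
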