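# On-disk dialects: tab-separated text throughout. Expression matrices carry
# a header row of sample IDs and a named identifier column of Entrez-style
# gene IDs; labels are sample_id<TAB>class with a header; pathways are GMT;
# the graph is a headerless two-column edge list.

#' Read a gene expression matrix from a TSV file
#'
#' First row holds sample IDs, one row per gene, with gene identifiers in
#' the column named `id_column`. Blank or NA identifiers are preserved as
#' missing markers for [collapse_gene_ids()] to drop; values are validated
#' as numeric and complete.
#'
#' @param path file path.
#' @param id_column name of the identifier column (default `"gene_id"`).
#' @return A raw [expression_matrix()] (`normalized = FALSE`), row order
#'   preserved.
#' @export
read_expression <- function(path, id_column = "gene_id") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  if (!id_column %in% names(df))
    stop("identifier column '", id_column, "' not found in ", path)
  ids <- as.character(df[[id_column]])
  val_idx <- which(names(df) != id_column)
  val_cols <- names(df)[val_idx]
  if (anyDuplicated(val_cols))
    stop("duplicate sample IDs in header of ", path)
  vals <- matrix(NA_real_, nrow(df), length(val_cols))
  for (j in seq_along(val_idx)) {
    raw <- df[[val_idx[j]]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric expression value at row ", bad[1],
           ", column '", val_cols[j], "' of ", path,
           " ('", raw[bad[1]], "')")
    vals[, j] <- v
  }
  expression_matrix(vals, ids, val_cols, normalized = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Values are printed with 17 significant digits so that a read/write
#' round trip reproduces them to full double precision.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param id_column identifier column name to use in the header.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  stopifnot(inherits(x, "expression_matrix"))
  txt <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  out <- cbind(ifelse(is.na(x$gene_ids), "", x$gene_ids), txt)
  colnames(out) <- c(id_column, x$sample_ids)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Two tab-separated columns with a header: sample ID, class label.
#'
#' @param path file path.
#' @param class_order optional explicit class ordering.
#' @return A [sample_classes()] factor.
#' @export
read_labels <- function(path, class_order = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("label file needs two columns: ", path)
  sample_classes(df[[2]], sample_ids = df[[1]], class_order = class_order)
}

#' Write sample class labels
#' @param classes a [sample_classes()] factor.
#' @param path output path.
#' @export
write_labels <- function(classes, path) {
  df <- data.frame(sample_id = names(classes),
                   class = as.character(classes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Broad GMT dialect: per line, pathway ID, descriptive name, then member
#' gene IDs, all tab-separated. Duplicate genes within a line are collapsed.
#'
#' @param path file path.
#' @return A [pathway_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  ids <- vapply(fields, `[[`, "", 1L)
  nms <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(genes) <- ids
  pathway_set(genes, pathway_names = nms)
}

#' Write a pathway set in GMT format
#' @param ps a [pathway_set()].
#' @param path output path.
#' @export
write_gmt <- function(ps, path) {
  stopifnot(inherits(ps, "pathway_set"))
  lines <- vapply(names(ps$genes), function(id) {
    paste(c(id, ps$pathway_names[[id]], ps$genes[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed graph from a two-column edge list
#'
#' Headerless TSV, source gene ID then target gene ID; direction is
#' column 1 -> column 2. Duplicate lines are collapsed with a message.
#'
#' @param path file path.
#' @return A [gene_graph()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty edge list: ", path)
    return(suppressWarnings(gene_graph(matrix(character(0), ncol = 2))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed edge-list line ", bad[1], " in ", path,
         " (expected 2 tab-separated fields)")
  edges <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  gene_graph(edges)
}

#' Write a directed graph as a two-column edge list
#' @param graph a [gene_graph()].
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "gene_graph"))
  writeLines(paste(graph$edges[, 1], graph$edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Write a pathway activity matrix to TSV
#' @param act an activity matrix from [infer_activity_matrix()].
#' @param path output path.
#' @export
write_activity <- function(act, path) {
  stopifnot(inherits(act, "activity_matrix"))
  txt <- matrix(sprintf("%.17g", act$values), nrow = nrow(act$values))
  out <- cbind(rownames(act$values), txt)
  colnames(out) <- c("pathway_id", colnames(act$values))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pathway ranking to TSV
#' @param ranking a ranking from [rank_and_select()].
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "pathway_ranking"))
  df <- ranking$table
  df$statistic <- sprintf("%.17g", df$statistic)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write diffused gene weights to TSV
#' @param w a weight vector from [random_walk_with_restart()] or
#'   [initial_weights()].
#' @param path output path.
#' @export
write_weights <- function(w, path) {
  df <- data.frame(gene_id = names(w), weight = sprintf("%.17g", w))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
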