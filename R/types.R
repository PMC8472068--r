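#' Construct an expression matrix
#'
#' A genes-by-samples matrix of real expression values keyed by gene ID
#' (Entrez-style, handled as opaque strings) and sample ID, carrying a flag
#' that records whether rows have been z-score normalized. Raw matrices (as
#' read from disk) may contain missing or repeated gene IDs; these must be
#' resolved with [collapse_gene_ids()] before any downstream step.
#'
#' @param values numeric matrix, rows = genes, columns = samples.
#' @param gene_ids character vector of gene identifiers, one per row.
#'   `NA` marks a missing identifier (permitted only in raw matrices).
#' @param sample_ids character vector of unique sample names, one per column.
#' @param normalized logical; `TRUE` once rows are z-scored.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `normalized`.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids,
                              normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("column count (", ncol(values), ") != number of sample ids (",
         length(sample_ids), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(is.na(sample_ids)) || any(sample_ids == ""))
    stop("sample IDs must be non-empty")
  if (any(!is.finite(values) & !is.na(values)))
    stop("expression values must be finite")
  if (anyNA(values))
    stop("missing expression values are not permitted")
  if (isTRUE(normalized)) {
    if (anyNA(gene_ids) || anyDuplicated(gene_ids))
      stop("a normalized matrix must have unique, non-missing gene IDs")
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         normalized = isTRUE(normalized)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a sample class labelling
#'
#' Maps each sample ID to one class label. The class order is deterministic:
#' either given explicitly or taken as the sorted set of distinct labels.
#'
#' @param labels character vector of class labels, named by sample ID (or
#'   with `sample_ids` supplied separately).
#' @param sample_ids optional character vector of sample IDs.
#' @param class_order optional explicit ordering of the distinct labels.
#' @return A named factor of class labels with class `sample_classes`.
#' @export
sample_classes <- function(labels, sample_ids = names(labels),
                           class_order = NULL) {
  labels <- as.character(labels)
  if (is.null(sample_ids))
    stop("sample IDs required (names of `labels` or `sample_ids=`)")
  sample_ids <- as.character(sample_ids)
  if (length(labels) != length(sample_ids))
    stop("labels and sample_ids differ in length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in labels")
  if (anyNA(labels) || any(labels == ""))
    stop("every sample needs a non-empty class label")
  if (is.null(class_order)) class_order <- sort(unique(labels))
  if (!setequal(class_order, unique(labels)))
    stop("class_order must list exactly the distinct labels")
  f <- factor(labels, levels = class_order)
  names(f) <- sample_ids
  class(f) <- c("sample_classes", "factor")
  f
}

# align labels to a sample-ID vector; errors on unlabelled samples and
# enforces >= 2 classes with >= 2 samples each
align_classes <- function(classes, sample_ids, min_per_class = 2L) {
  if (!all(sample_ids %in% names(classes)))
    stop("samples without class label: ",
         paste(setdiff(sample_ids, names(classes)), collapse = ", "))
  cls <- factor(as.character(classes[sample_ids]),
                levels = levels(classes))
  cls <- droplevels(cls)
  tab <- table(cls)
  if (length(tab) < 2L) stop("need at least 2 classes, got ", length(tab))
  if (any(tab < min_per_class))
    stop("every class needs >= ", min_per_class, " samples; too small: ",
         paste(names(tab)[tab < min_per_class], collapse = ", "))
  names(cls) <- sample_ids
  cls
}

#' Construct a pathway set
#'
#' @param genes named list of character vectors: pathway ID -> member gene
#'   IDs. Within-pathway duplicates are collapsed.
#' @param pathway_names optional character vector of descriptive names,
#'   aligned with `genes` (defaults to the IDs).
#' @return Object of class `pathway_set`.
#' @export
pathway_set <- function(genes, pathway_names = NULL) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("pathway IDs must be unique and non-missing")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0L))
    stop("pathways with no member genes: ",
         paste(names(genes)[lengths(genes) == 0L], collapse = ", "))
  if (is.null(pathway_names)) pathway_names <- names(genes)
  pathway_names <- setNames(as.character(pathway_names), names(genes))
  structure(list(genes = genes, pathway_names = pathway_names),
            class = "pathway_set")
}

#' @export
length.pathway_set <- function(x) length(x$genes)

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway_set: %d pathways, median size %d genes\n",
              length(x$genes), as.integer(stats::median(lengths(x$genes)))))
  invisible(x)
}

#' Construct a directed gene graph
#'
#' Nodes are gene IDs; edges are ordered (source, target) pairs. Duplicate
#' edges are collapsed (with a message reporting how many were dropped);
#' self-loops are kept but reported.
#'
#' @param edges two-column character matrix (or data frame), source then
#'   target gene ID.
#' @param nodes optional node set; defaults to the union of edge endpoints.
#'   Every edge endpoint must be a node.
#' @return Object of class `gene_graph` with elements `nodes` (character)
#'   and `edges` (two-column character matrix).
#' @export
gene_graph <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) != 2L) stop("edges must have exactly 2 columns")
  mode(edges) <- "character"
  dup <- duplicated(paste(edges[, 1], edges[, 2], sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  if (is.null(nodes)) nodes <- unique(c(edges[, 1], edges[, 2]))
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0L) warning("graph has no nodes")
  missing_ep <- setdiff(c(edges[, 1], edges[, 2]), nodes)
  if (length(missing_ep))
    stop("edge endpoints not in node set: ",
         paste(missing_ep, collapse = ", "))
  loops <- sum(edges[, 1] == edges[, 2])
  if (loops > 0) message(loops, " self-loop(s) retained")
  colnames(edges) <- c("source", "target")
  structure(list(nodes = nodes, edges = edges), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
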