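# Diffusion of differential-expression evidence over the directed gene
# graph. Initial weights come from min-max scaled |statistic|; the walk is
# the usual random walk with restart on the row-normalized adjacency matrix
# augmented with a single virtual ground node that absorbs dangling
# (zero-out-degree) genes and redistributes uniformly, keeping every row
# stochastic.

#' Initial gene weights from differential-expression statistics
#'
#' Graph nodes with an expression statistic receive
#' (|F| - min|F|) / (max|F| - min|F|), the min and max taken over graph-node
#' genes; nodes absent from the expression data get weight 0. If all
#' statistics are equal the surviving nodes share uniform weight. The result
#' is L1-normalized to a restart distribution summing to one.
#'
#' @param stats a `gene_stat_table` from [gene_stats()].
#' @param graph a [gene_graph()].
#' @return Named numeric vector over `graph$nodes`, nonnegative, summing
#'   to 1, with attribute `kind = "initial"`.
#' @export
initial_weights <- function(stats, graph) {
  stopifnot(inherits(graph, "gene_graph"))
  if (length(graph$nodes) == 0L) stop("graph has no nodes")
  f <- abs(stats$statistic)[match(graph$nodes, stats$gene_id)]
  has_data <- !is.na(f)
  if (!any(has_data))
    stop("no graph node has expression data")
  lo <- min(f[has_data]); hi <- max(f[has_data])
  raw <- numeric(length(graph$nodes))
  raw[has_data] <- if (hi > lo) (f[has_data] - lo) / (hi - lo) else 1
  s <- sum(raw)
  w <- if (s > 0) raw / s else
    ifelse(has_data, 1 / sum(has_data), 0)
  names(w) <- graph$nodes
  attr(w, "kind") <- "initial"
  w
}

#' Row-stochastic transition matrix with a virtual ground node
#'
#' Builds the binary adjacency matrix of the directed graph, appends one
#' ground node, wires every dangling real node to ground and ground back to
#' every real node, then row-normalizes.
#'
#' @param graph a [gene_graph()].
#' @return A list of class `transition_matrix`: sparse row-stochastic
#'   matrix `M` ((n+1) x (n+1), ground node last), node IDs `nodes`, and
#'   `ground` index.
#' @export
build_transition <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  n <- length(graph$nodes)
  if (n == 0L) stop("graph has no nodes")
  i <- match(graph$edges[, 1], graph$nodes)
  j <- match(graph$edges[, 2], graph$nodes)
  out_deg <- tabulate(i, nbins = n)
  dangling <- which(out_deg == 0L)
  i <- c(i, dangling, rep(n + 1L, n))
  j <- c(j, rep(n + 1L, length(dangling)), seq_len(n))
  A <- sparseMatrix(i = i, j = j, x = 1, dims = c(n + 1L, n + 1L))
  M <- Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
  structure(list(M = M, nodes = graph$nodes, ground = n + 1L),
            class = "transition_matrix")
}

#' Random walk with restart to its fixed point
#'
#' Iterates `W[t+1] = (1 - r) t(M) W[t] + r W0` from `W[0] = W0` until the
#' L1 change falls below `tol`, then drops the ground-node entry and
#' re-normalizes over real nodes. `W0` doubles as restart distribution and
#' starting state.
#'
#' @param transition a `transition_matrix` from [build_transition()].
#' @param w0 initial weight vector over real nodes (sums to 1); ground
#'   carries no restart mass.
#' @param r restart probability in (0, 1]; default 0.7.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter iteration cap; default 10000.
#' @return Named numeric vector over real nodes summing to 1, attribute
#'   `kind = "stationary"`, plus `iterations` and `residual` attributes.
#' @export
random_walk_with_restart <- function(transition, w0, r = 0.7,
                                     tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(transition, "transition_matrix"))
  if (!(r > 0 && r <= 1)) stop("restart probability r must be in (0, 1]")
  nodes <- transition$nodes
  n <- length(nodes)
  if (length(w0) != n) stop("w0 length does not match graph node count")
  if (!is.null(names(w0)) && !identical(names(w0), nodes))
    w0 <- w0[nodes]
  if (any(w0 < 0) || abs(sum(w0) - 1) > 1e-8)
    stop("w0 must be a probability distribution over the graph nodes")
  Mt <- Matrix::t(transition$M)
  w_ext <- c(as.numeric(w0), 0)
  w0_ext <- w_ext
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w_new <- as.numeric((1 - r) * (Mt %*% w_ext)) + r * w0_ext
    delta <- sum(abs(w_new - w_ext))
    w_ext <- w_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop("random walk did not converge in ", max_iter,
           " iterations (last L1 residual ", format(delta), ")")
  }
  w <- w_ext[seq_len(n)]
  w <- w / sum(w)
  names(w) <- nodes
  attr(w, "kind") <- "stationary"
  attr(w, "iterations") <- iter
  attr(w, "residual") <- sum(abs(
    ((1 - r) * as.numeric(Mt %*% w_ext) + r * w0_ext) - w_ext))
  w
}
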