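#' Gene-gene Pearson correlation matrix
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param samples which samples to correlate over: \code{"all"} (default,
#'   cases and controls pooled), \code{"case"} or \code{"control"}.
#' @return symmetric correlation matrix with unit diagonal over the genes
#'   with non-zero variance (zero-variance genes dropped with a warning).
#' @export
pearson_matrix <- function(expr, samples = c("all", "case", "control")) {
  samples <- match.arg(samples)
  ids <- switch(samples, all = sample_ids(expr), case = case_ids(expr),
                control = control_ids(expr))
  if (length(ids) < 3L)
    stop("need >= 3 samples to estimate correlations (have ", length(ids), ")")
  m <- expr$values[, ids, drop = FALSE]
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(m))
  attr(r, "built_on") <- samples
  r
}

#' Build the thresholded co-expression graph
#'
#' Nodes are the genes of the correlation matrix; an undirected edge joins i
#' and j iff |r_ij| >= threshold (i != j). The signed correlation is kept as
#' the edge weight, so negative edges — essential for fight-club hubs —
#' survive thresholding. Isolated nodes stay in the node set.
#'
#' @param corr correlation matrix from \code{\link{pearson_matrix}}.
#' @param threshold absolute-correlation cut-off in (0, 1). The method
#'   itself does not fix this value; it must be chosen (or see
#'   \code{\link{auto_threshold}}) and is recorded on the graph.
#' @return a \code{CorrelationGraph}: an igraph object with edge attribute
#'   \code{weight} (signed r) and graph attributes \code{threshold} and
#'   \code{built_on}.
#' @export
build_graph <- function(corr, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  adj <- corr
  diag(adj) <- 0
  adj[abs(adj) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "built_on",
                              attr(corr, "built_on") %||% "all")
  class(g) <- c("CorrelationGraph", class(g))
  g
}

#' Density-capped default correlation threshold
#'
#' Scans the grid 0.50, 0.55, ..., 0.95 and returns the smallest threshold
#' whose graph density is at most \code{max_density}; falls back to the
#' largest grid value with a warning if none qualifies.
#'
#' @param corr correlation matrix.
#' @param grid candidate thresholds.
#' @param max_density density cap (default 0.1).
#' @return the selected threshold.
#' @export
auto_threshold <- function(corr, grid = seq(0.5, 0.95, by = 0.05),
                           max_density = 0.1) {
  n <- nrow(corr)
  n_pairs <- n * (n - 1) / 2
  a <- abs(corr[upper.tri(corr)])
  for (thr in sort(grid)) {
    if (sum(a >= thr) / n_pairs <= max_density) return(thr)
  }
  warning("no grid threshold meets the density cap; using ", max(grid))
  max(grid)
}

#' Largest connected component of a graph
#'
#' @param graph a \code{CorrelationGraph} (or any igraph).
#' @return the induced subgraph on the largest component; size ties broken
#'   by the lexicographically smallest member vertex name.
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    nm <- igraph::V(graph)$name
    min_name <- vapply(best, function(k) min(nm[comp$membership == k]),
                       character(1))
    best <- best[order(min_name)][1L]
  }
  sub <- igraph::induced_subgraph(graph, which(comp$membership == best))
  for (a in igraph::graph_attr_names(graph))
    sub <- igraph::set_graph_attr(sub, a, igraph::graph_attr(graph, a))
  class(sub) <- class(graph)
  sub
}

#' Export a graph as a weighted edge list
#'
#' @param graph a \code{CorrelationGraph}.
#' @param path output path (tab-delimited: gene_i, gene_j, r).
#' @return invisibly, \code{path}.
#' @export
write_graph_edges <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  out <- data.frame(gene_i = el[, 1L], gene_j = el[, 2L],
                    r = igraph::E(graph)$weight %||%
                        rep(NA_real_, igraph::ecount(graph)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
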