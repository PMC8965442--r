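# Targeted node-removal robustness: how the average shortest path of the
# co-expression network degrades as nodes of a given class are removed.

#' Average shortest path of a graph
#'
#' Unweighted breadth-first distances averaged over all unordered reachable
#' pairs. On a disconnected graph the path is computed on the largest
#' component (with a message).
#'
#' @param graph a \code{CorrelationGraph} (or any igraph).
#' @return the mean shortest-path length.
#' @export
average_shortest_path <- function(graph) {
  if (igraph::vcount(graph) < 2L) stop("need >= 2 nodes")
  if (!igraph::is_connected(graph)) {
    message("graph disconnected; average shortest path on largest component")
    graph <- largest_component(graph)
    if (igraph::vcount(graph) < 2L)
      stop("largest component has < 2 nodes")
  }
  igraph::mean_distance(graph, weights = NA, directed = FALSE)
}

#' Node-removal robustness curve
#'
#' Removes a growing fraction of nodes and records the average shortest path
#' of the largest remaining component after each step. Class strategies
#' (\code{date}, \code{party}, \code{fight_club}, \code{switch}) remove
#' nodes of that class in seeded-random order; \code{random} removes
#' uniformly from all nodes; \code{degree} removes by descending degree.
#'
#' @param graph a \code{CorrelationGraph}.
#' @param cartography a \code{NodeCartography} for the graph's nodes.
#' @param strategy one of \code{"random"}, \code{"date"}, \code{"party"},
#'   \code{"fight_club"}, \code{"switch"}, \code{"degree"}.
#' @param fractions strictly increasing removal fractions in [0, 1],
#'   relative to the total node count; fractions exceeding the strategy's
#'   node pool are truncated with a warning.
#' @param seed RNG seed for the removal order.
#' @return a \code{RobustnessCurve} data.frame: strategy, fraction,
#'   n_removed, asp, seed. The curve is truncated (with a warning) once
#'   fewer than 2 nodes remain reachable.
#' @export
removal_curve <- function(graph, cartography,
                          strategy = c("random", "date", "party",
                                       "fight_club", "switch", "degree"),
                          fractions = seq(0, 0.5, by = 0.05), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(all(diff(fractions) > 0), all(fractions >= 0),
            all(fractions <= 1))
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  pool <- switch(strategy,
    random = nodes,
    degree = nodes[order(-igraph::degree(graph), nodes)],
    switch = cartography$node[cartography$is_switch],
    cartography$node[cartography$hub_class == strategy])
  if (!length(pool)) stop("no node eligible for strategy '", strategy, "'")
  if (strategy != "degree")
    pool <- with_seed(seed, sample(pool))
  max_frac <- length(pool) / n
  if (any(fractions > max_frac)) {
    warning(sprintf("fractions above pool limit %.3f truncated", max_frac))
    fractions <- fractions[fractions <= max_frac]
  }
  out <- data.frame(strategy = character(0), fraction = numeric(0),
                    n_removed = integer(0), asp = numeric(0),
                    seed = integer(0))
  for (f in fractions) {
    n_remove <- floor(f * n)
    g <- igraph::delete_vertices(graph, pool[seq_len(n_remove)])
    asp <- tryCatch(suppressMessages(average_shortest_path(g)),
                    error = function(e) NA_real_)
    if (is.na(asp)) {
      warning("curve truncated at fraction ", f,
              ": fewer than 2 reachable nodes remain")
      break
    }
    out <- rbind(out, data.frame(strategy = strategy, fraction = f,
                                 n_removed = n_remove, asp = asp,
                                 seed = as.integer(seed)))
  }
  class(out) <- c("RobustnessCurve", "data.frame")
  out
}

#' Area under a robustness curve
#'
#' Trapezoidal area of asp over fraction; a scalar summary used to compare
#' removal strategies on a common fraction grid.
#'
#' @param curve a \code{RobustnessCurve}.
#' @return the trapezoidal AUC.
#' @export
robustness_auc <- function(curve) {
  stopifnot(nrow(curve) >= 2L)
  x <- curve$fraction; y <- curve$asp
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}
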