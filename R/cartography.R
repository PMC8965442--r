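# Heat cartography: within-module degree z-score (Zg), clusterphobic
# coefficient (Kpi), average neighbour correlation (APCC), the R1-R7 role
# plane, the date/party/fight-club hub taxonomy and the switch-gene call.

#' Within-module degree z-score (Zg)
#'
#' For node i in community c, Zg(i) = (kappa_i - mean(kappa_c)) /
#' sd(kappa_c), where kappa_i counts i's edges to nodes of its own community
#' and the moments are taken over c's members (population sd). A community
#' with zero degree spread gives Zg = 0 for its members.
#'
#' @param graph a \code{CorrelationGraph}.
#' @param communities a \code{CommunityAssignment} covering every node.
#' @return named numeric vector of Zg values.
#' @export
within_module_degree_z <- function(graph, communities) {
  nodes <- igraph::V(graph)$name
  cl <- communities$cluster_of
  miss <- setdiff(nodes, names(cl))
  if (length(miss))
    stop("node(s) without community: ", paste(miss, collapse = ", "))
  cl <- cl[nodes]
  kappa <- intra_degree(graph, cl)
  zg <- stats::setNames(numeric(length(nodes)), nodes)
  for (c_idx in unique(cl)) {
    members <- nodes[cl == c_idx]
    k <- kappa[members]
    mu <- mean(k)
    sdev <- sqrt(mean((k - mu)^2))
    zg[members] <- if (sdev == 0) 0 else (k - mu) / sdev
  }
  zg
}

# per-node count of edges to same-community nodes
intra_degree <- function(graph, cl) {
  nodes <- igraph::V(graph)$name
  kappa <- stats::setNames(integer(length(nodes)), nodes)
  el <- igraph::as_edgelist(graph)
  if (nrow(el)) {
    same <- cl[el[, 1L]] == cl[el[, 2L]]
    for (v in c(el[same, 1L], el[same, 2L]))
      kappa[v] <- kappa[v] + 1L
  }
  kappa
}

#' Clusterphobic coefficient (Kpi)
#'
#' Kpi(i) = 1 - (k_in(i) / k_tot(i))^2, with k_in the edges inside i's
#' community and k_tot all of i's edges. Near 1 means most links leave the
#' module; all-internal nodes score 0. Isolated nodes score 0 by convention.
#'
#' @inheritParams within_module_degree_z
#' @return named numeric vector of Kpi values in [0, 1].
#' @export
clusterphobic_coefficient <- function(graph, communities) {
  nodes <- igraph::V(graph)$name
  cl <- communities$cluster_of
  miss <- setdiff(nodes, names(cl))
  if (length(miss))
    stop("node(s) without community: ", paste(miss, collapse = ", "))
  cl <- cl[nodes]
  k_tot <- igraph::degree(graph)
  k_in <- intra_degree(graph, cl)
  kpi <- ifelse(k_tot == 0, 0, 1 - (k_in / k_tot)^2)
  stats::setNames(as.numeric(kpi), nodes)
}

#' Average Pearson correlation with network neighbours (APCC)
#'
#' APCC(i) is the mean, over i's graph neighbours j, of the Pearson
#' correlation between the expression profiles of i and j. Degree-0 nodes
#' get NA (excluded from hub classes).
#'
#' @param expr an \code{ExpressionMatrix} containing every graph node.
#' @param graph a \code{CorrelationGraph}.
#' @return named numeric vector of APCC values in [-1, 1] (NA for isolated
#'   nodes).
#' @export
apcc <- function(expr, graph) {
  nodes <- igraph::V(graph)$name
  miss <- setdiff(nodes, gene_ids(expr))
  if (length(miss))
    stop("graph node(s) absent from expression: ",
         paste(miss, collapse = ", "))
  r <- stats::cor(t(expr$values[nodes, , drop = FALSE]))
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)[nodes, nodes]
  deg <- rowSums(adj)
  out <- rowSums(r * adj) / ifelse(deg == 0, NA_real_, deg)
  stats::setNames(as.numeric(out), nodes)
}

#' Full node cartography with hub classes, regions and switch calls
#'
#' Hub taxonomy by neighbour correlation: \code{fight_club} if APCC < 0,
#' \code{party} if APCC >= \code{party_apcc}, \code{date} if 0 <= APCC <
#' \code{party_apcc} (APCC = 0 is a date hub by convention); isolated nodes
#' are \code{none}. Regions partition the (Kpi, Zg) plane: non-hub rows
#' (Zg < \code{zg_hub_row}) split at Kpi = 0.05, 0.62, 0.8 into R1-R4, hub
#' rows at Kpi = 0.30, 0.75 into R5-R7. A node with Zg > \code{zg_network_hub}
#' is additionally flagged a network hub. Switch genes satisfy all of
#' Zg < \code{zg_max}, Kpi > \code{kpi_min}, APCC < \code{apcc_max}
#' (strict inequalities).
#'
#' @param graph a \code{CorrelationGraph}.
#' @param communities a \code{CommunityAssignment}.
#' @param expr the \code{ExpressionMatrix} the graph was built from.
#' @param zg_max,kpi_min,apcc_max switch thresholds (defaults 2.5, 0.8, 0).
#' @param zg_network_hub Zg above which a node is a network hub (default 5).
#' @param party_apcc date/party split on APCC (default 0.5).
#' @param zg_hub_row Zg row boundary of the region plane (default 2.5).
#' @return a \code{NodeCartography} data.frame: node, community, zg, kpi,
#'   apcc, region, hub_class, is_network_hub, is_switch.
#' @export
classify_nodes <- function(graph, communities, expr,
                           zg_max = 2.5, kpi_min = 0.8, apcc_max = 0,
                           zg_network_hub = 5, party_apcc = 0.5,
                           zg_hub_row = 2.5) {
  nodes <- igraph::V(graph)$name
  zg <- within_module_degree_z(graph, communities)
  kpi <- clusterphobic_coefficient(graph, communities)
  ap <- apcc(expr, graph)
  hub_class <- ifelse(is.na(ap), "none",
                ifelse(ap < 0, "fight_club",
                ifelse(ap >= party_apcc, "party", "date")))
  region <- character(length(nodes))
  low <- zg < zg_hub_row
  region[low] <- as.character(cut(kpi[low], c(-Inf, 0.05, 0.62, 0.8, Inf),
                                  labels = c("R1", "R2", "R3", "R4")))
  region[!low] <- as.character(cut(kpi[!low], c(-Inf, 0.30, 0.75, Inf),
                                   labels = c("R5", "R6", "R7")))
  is_switch <- is_switch_node(zg, kpi, ap, zg_max, kpi_min, apcc_max)
  res <- data.frame(node = nodes,
                    community = unname(communities$cluster_of[nodes]),
                    zg = unname(zg), kpi = unname(kpi), apcc = unname(ap),
                    region = region, hub_class = hub_class,
                    is_network_hub = unname(zg > zg_network_hub),
                    is_switch = unname(is_switch),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("NodeCartography", "data.frame")
  res
}

# the switch-gene rule: all three thresholds strict, NA APCC never switches
is_switch_node <- function(zg, kpi, apcc, zg_max = 2.5, kpi_min = 0.8,
                           apcc_max = 0) {
  !is.na(apcc) & zg < zg_max & kpi > kpi_min & apcc < apcc_max
}

#' Switch genes from a node cartography
#'
#' @param cartography a \code{NodeCartography} from
#'   \code{\link{classify_nodes}}.
#' @return character vector of switch gene ids (possibly empty, with a
#'   warning).
#' @export
call_switch_genes <- function(cartography) {
  stopifnot(inherits(cartography, "NodeCartography"))
  sw <- cartography$node[cartography$is_switch]
  if (!length(sw)) warning("no switch genes called")
  sw
}

#' Bicluster switch-gene expression
#'
#' Average-linkage hierarchical clustering of the switch genes (rows, using
#' correlation distance 1 - r) and of the samples (columns, Euclidean
#' distance on per-gene z-scored expression).
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param switch_genes >= 2 gene ids present in \code{expr}.
#' @return a \code{Bicluster}: list with \code{row_order}, \code{col_order}
#'   (id permutations), \code{linkage_rows}, \code{linkage_cols} (hclust
#'   trees), and \code{matrix} (z-scored expression, reordered).
#' @export
bicluster_switch <- function(expr, switch_genes) {
  if (length(switch_genes) < 2L)
    stop("need >= 2 switch genes to bicluster")
  miss <- setdiff(switch_genes, gene_ids(expr))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  m <- expr$values[switch_genes, , drop = FALSE]
  z <- zscore_rows(m)
  d_rows <- stats::as.dist(1 - stats::cor(t(m)))
  h_rows <- stats::hclust(d_rows, method = "average")
  h_cols <- stats::hclust(stats::dist(t(z)), method = "average")
  structure(list(row_order = switch_genes[h_rows$order],
                 col_order = sample_ids(expr)[h_cols$order],
                 linkage_rows = h_rows, linkage_cols = h_cols,
                 matrix = z[h_rows$order, h_cols$order, drop = FALSE]),
            class = "Bicluster")
}
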