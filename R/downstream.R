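# Downstream interpretation of switch genes: hypergeometric
# over-representation, regulator ranking, and multi-list overlap tables.

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query (e.g. the switch genes) hits
#' the set more often than chance: upper-tail hypergeometric p = P(X >=
#' overlap) with population \code{|background|}, successes = set members in
#' the background, draws = \code{|query|}. Zero-overlap sets score p = 1 by
#' convention; sets with no member in the background are skipped. BH
#' correction across the tested sets.
#'
#' @param query gene ids; must be a subset of \code{background}.
#' @param background universe of measured gene ids (defaults in the pipeline
#'   to the genes surviving \code{\link{preprocess}}).
#' @param collection a \code{GeneSetCollection} from \code{\link{read_gmt}}.
#' @return an \code{EnrichmentResult} data.frame: set, overlap_count,
#'   set_size, query_size, background_size, p_value, q_value; sorted by
#'   p_value.
#' @export
enrich <- function(query, background, collection) {
  query <- unique(query); background <- unique(background)
  if (!length(query)) stop("empty query")
  bad <- setdiff(query, background)
  if (length(bad))
    stop("query gene(s) not in background: ", paste(bad, collapse = ", "))
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$members, background)
    if (!length(members)) return(NULL)   # no background overlap: skipped
    ov <- length(intersect(members, query))
    p <- if (ov == 0) 1 else
      stats::phyper(ov - 1L, length(members),
                    length(background) - length(members), length(query),
                    lower.tail = FALSE)
    data.frame(set = nm, overlap_count = ov, set_size = length(members),
               query_size = length(query),
               background_size = length(background), p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene set overlaps the background")
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Rank regulators of the switch genes by network topology
#'
#' Restricts an interaction table to edges targeting switch genes, keeps
#' regulators supported by at least \code{min_sources} distinct source tags
#' (the multi-database consensus), and ranks them by degree (number of
#' switch-gene targets) then betweenness centrality on the bipartite
#' regulator-gene graph (undirected, unnormalised), then id.
#'
#' @param interactions an \code{InteractionTable}.
#' @param switch_genes character vector of switch gene ids.
#' @param min_sources required number of distinct supporting sources
#'   (default 1; use 3 for a three-database consensus).
#' @return a \code{RegulatorRanking} data.frame: regulator, kind, degree,
#'   betweenness, n_sources, sources.
#' @export
rank_regulators <- function(interactions, switch_genes, min_sources = 1L) {
  stopifnot(inherits(interactions, "InteractionTable"),
            nrow(interactions) > 0L)
  edges <- as.data.frame(interactions)
  edges <- edges[edges$gene %in% switch_genes, , drop = FALSE]
  if (!nrow(edges)) {
    warning("no regulator targets a switch gene")
    return(empty_ranking(attr(interactions, "kind")))
  }
  src <- tapply(edges$source, edges$regulator,
                function(s) sort(unique(s)), simplify = FALSE)
  keep <- names(src)[lengths(src) >= min_sources]
  edges <- edges[edges$regulator %in% keep, , drop = FALSE]
  if (!nrow(edges)) {
    warning("no regulator passes the ", min_sources, "-source consensus")
    return(empty_ranking(attr(interactions, "kind")))
  }
  pairs <- unique(edges[, c("regulator", "gene")])
  # regulators and genes share the node space; prefix to avoid id clashes
  g <- igraph::graph_from_edgelist(
    cbind(paste0("reg:", pairs$regulator), paste0("gene:", pairs$gene)),
    directed = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  deg <- table(pairs$regulator)
  regs <- sort(unique(pairs$regulator))
  res <- data.frame(
    regulator = regs, kind = attr(interactions, "kind"),
    degree = as.integer(deg[regs]),
    betweenness = unname(btw[paste0("reg:", regs)]),
    n_sources = lengths(src[regs]),
    sources = vapply(src[regs], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-res$degree, -res$betweenness, res$regulator), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("RegulatorRanking", "data.frame")
  res
}

empty_ranking <- function(kind) {
  res <- data.frame(regulator = character(0), kind = character(0),
                    degree = integer(0), betweenness = numeric(0),
                    n_sources = integer(0), sources = character(0))
  class(res) <- c("RegulatorRanking", "data.frame")
  res
}

#' Multi-list overlap (Venn) table
#'
#' For named gene lists (e.g. switch genes per dataset), tabulates every
#' item's membership across the lists and summarises how many items are
#' shared by exactly n lists.
#'
#' @param lists named list (>= 2) of character vectors.
#' @return an \code{OverlapTable}: list with \code{items} (data.frame item,
#'   n_lists, list_names) and \code{summary} (data.frame n, count); counts
#'   sum to the size of the union.
#' @export
shared_between <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L,
            !is.null(names(lists)), all(nzchar(names(lists))))
  lists <- lapply(lists, unique)
  universe <- sort(unique(unlist(lists)))
  membership <- vapply(lists, function(l) universe %in% l,
                       logical(length(universe)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(universe))
  n_lists <- rowSums(membership)
  items <- data.frame(
    item = universe, n_lists = as.integer(n_lists),
    list_names = apply(membership, 1L, function(m)
      paste(names(lists)[m], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
  items <- items[order(-items$n_lists, items$item), , drop = FALSE]
  rownames(items) <- NULL
  summary <- as.data.frame(table(n = factor(n_lists,
                                            levels = seq_along(lists))),
                           stringsAsFactors = FALSE)
  names(summary) <- c("n", "count")
  summary$n <- as.integer(summary$n)
  structure(list(items = items, summary = summary), class = "OverlapTable")
}
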