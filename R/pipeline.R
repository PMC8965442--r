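#' Pipeline run configuration
#'
#' Collects every tunable of the switch-gene pipeline with the method's
#' default thresholds: switch calls at Zg < 2.5, Kpi > 0.8, APCC < 0;
#' network hubs at Zg > 5.
#'
#' @param dataset free-text run label.
#' @param fold_change linear fold-change threshold for the differential
#'   filter (per-dataset setting; published analyses used values in
#'   \{1.5, 1.75, 2, 2.5, 3, 4, 4.5\}).
#' @param alpha FDR level of the filter (1 disables the test).
#' @param min_mean,min_fraction_expressed \code{\link{preprocess}} settings.
#' @param correlation_threshold |r| edge cut-off in (0,1), or \code{"auto"}
#'   for the density-capped grid rule (\code{\link{auto_threshold}}). The
#'   choice is always recorded in the run log.
#' @param k number of communities, or \code{NULL} to pick k from the SSE
#'   scree elbow over \code{k_range}.
#' @param k_range candidate k values for the scree.
#' @param replicates k-means restarts per k.
#' @param zg_max,kpi_min,apcc_max switch-call thresholds.
#' @param zg_network_hub network-hub threshold on Zg.
#' @param robustness_fractions removal fractions for the robustness stage
#'   (\code{NULL} derives a grid capped by the fight-club pool size).
#' @param seed master seed; each stochastic stage derives a named child
#'   seed from it.
#' @return a \code{RunConfig} list.
#' @export
run_config <- function(dataset = "run", fold_change = 2, alpha = 0.05,
                       min_mean = 1, min_fraction_expressed = 0.5,
                       correlation_threshold = "auto", k = NULL,
                       k_range = 2:10, replicates = 10L,
                       zg_max = 2.5, kpi_min = 0.8, apcc_max = 0,
                       zg_network_hub = 5, robustness_fractions = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(fold_change > 1, alpha > 0, alpha <= 1)
  if (!identical(correlation_threshold, "auto"))
    stopifnot(is.numeric(correlation_threshold),
              correlation_threshold > 0, correlation_threshold < 1)
  structure(cfg, class = "RunConfig")
}

#' Run the full switch-gene pipeline
#'
#' Executes filter -> network -> communities -> cartography -> switch calls
#' -> robustness on an expression matrix, and optionally enrichment,
#' regulator ranking and biclustering. All stage outputs are returned in a
#' single list; if \code{out_dir} is given they are also written as
#' delimited text together with the resolved configuration.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param config a \code{\link{run_config}}.
#' @param collection optional \code{GeneSetCollection} for enrichment of the
#'   switch genes (background = genes surviving preprocess).
#' @param interactions optional list of \code{InteractionTable}s for
#'   regulator ranking.
#' @param min_sources source consensus for regulator ranking.
#' @param out_dir optional output directory.
#' @return a \code{PipelineResult} list: expr_filtered, differential,
#'   retained, correlation_threshold, graph, communities (with sse_table and
#'   chosen k), cartography, switch_genes, bicluster (or NULL), robustness,
#'   enrichment (or NULL), regulators (or NULL), log (stage counts).
#' @export
run_pipeline <- function(expr, config = run_config(), collection = NULL,
                         interactions = NULL, min_sources = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(config, "RunConfig"))
  log <- list(dataset = config$dataset, n_genes_input = nrow(expr$values),
              n_samples = ncol(expr$values))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  expr_f <- stage("preprocess",
    preprocess(expr, config$min_mean, config$min_fraction_expressed))
  log$n_genes_expressed <- nrow(expr_f$values)

  diff <- stage("filter",
    differential_table(expr_f, config$fold_change, config$alpha))
  retained <- filter_genes(diff)
  if (length(retained) < 3L)
    stop("pipeline stage 'filter' failed: fewer than 3 genes retained; ",
         "relax fold_change/alpha", call. = FALSE)
  log$n_genes_retained <- length(retained)
  expr_r <- subset_expression(expr_f, genes = retained)

  corr <- stage("network", pearson_matrix(expr_r))
  thr <- if (identical(config$correlation_threshold, "auto"))
    auto_threshold(corr) else config$correlation_threshold
  log$correlation_threshold <- thr
  graph <- stage("network", build_graph(corr, thr))
  log$n_edges <- igraph::ecount(graph)

  nodes <- igraph::V(graph)$name
  km_seed <- child_seed(config$seed, "kmeans")
  if (is.null(config$k)) {
    k_range <- config$k_range[config$k_range <= length(nodes)]
    sse_tab <- stage("communities",
      scree(expr_r, nodes, k_range, config$replicates, km_seed))
    k <- stage("communities", choose_k(sse_tab))
  } else {
    sse_tab <- NULL
    k <- config$k
  }
  comm <- stage("communities",
    kmeans_profiles(expr_r, nodes, k, config$replicates, km_seed))
  log$k <- k

  carto <- stage("cartography",
    classify_nodes(graph, comm, expr_r, zg_max = config$zg_max,
                   kpi_min = config$kpi_min, apcc_max = config$apcc_max,
                   zg_network_hub = config$zg_network_hub))
  switch_genes <- suppressWarnings(call_switch_genes(carto))
  log$n_switch <- length(switch_genes)

  bic <- if (length(switch_genes) >= 2L)
    stage("bicluster", bicluster_switch(expr_r, switch_genes)) else NULL

  rob_seed <- child_seed(config$seed, "robustness")
  g_main <- largest_component(graph)
  carto_main <- carto[carto$node %in% igraph::V(g_main)$name, , drop = FALSE]
  fractions <- config$robustness_fractions
  if (is.null(fractions)) {
    pool <- sum(carto_main$hub_class == "fight_club")
    n <- igraph::vcount(g_main)
    step <- max(1 / n, 0.01)
    fractions <- seq(0, max(step, floor(0.8 * pool) / n), by = step)
  }
  rob <- stage("robustness", {
    strategies <- c("random", "degree",
                    intersect(c("fight_club", "date", "party"),
                              unique(carto_main$hub_class)))
    curves <- lapply(strategies, function(s)
      suppressWarnings(removal_curve(g_main, carto_main, s, fractions,
                                     rob_seed)))
    do.call(rbind, curves)
  })

  enr <- if (!is.null(collection) && length(switch_genes))
    stage("enrich", enrich(switch_genes, gene_ids(expr_f), collection))
  else NULL
  reg <- if (!is.null(interactions) && length(switch_genes))
    stage("regulators", lapply(interactions, rank_regulators,
                               switch_genes = switch_genes,
                               min_sources = min_sources))
  else NULL

  res <- structure(
    list(expr_filtered = expr_f, differential = diff, retained = retained,
         correlation_threshold = thr, graph = graph,
         sse_table = sse_tab, communities = comm, cartography = carto,
         switch_genes = switch_genes, bicluster = bic, robustness = rob,
         enrichment = enr, regulators = reg, config = config, log = log),
    class = "PipelineResult")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  l <- x$log
  cat(sprintf(paste0(
    "PipelineResult '%s': %d genes -> %d expressed -> %d retained\n",
    "  correlation threshold %.2f, %d edges, k = %d communities\n",
    "  %d switch genes called\n"),
    l$dataset, l$n_genes_input, l$n_genes_expressed, l$n_genes_retained,
    l$correlation_threshold, l$n_edges, l$k, l$n_switch))
  invisible(x)
}

#' Write all pipeline stage outputs to a directory
#'
#' @param result a \code{PipelineResult}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, \code{out_dir}.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(as.data.frame(result$differential), "differential.tsv")
  write_gene_list(result$retained, file.path(out_dir, "retained.txt"))
  write_graph_edges(result$graph, file.path(out_dir, "edges.tsv"))
  w(data.frame(node = names(result$communities$cluster_of),
               cluster = unname(result$communities$cluster_of)),
    "communities.tsv")
  if (!is.null(result$sse_table)) w(result$sse_table, "sse.tsv")
  w(as.data.frame(result$cartography), "cartography.tsv")
  write_gene_list(result$switch_genes, file.path(out_dir, "switch.txt"))
  w(as.data.frame(result$robustness), "robustness.tsv")
  if (!is.null(result$enrichment))
    w(as.data.frame(result$enrichment), "enrichment.tsv")
  cfg <- result$config
  cfg$robustness_fractions <-
    paste(cfg$robustness_fractions %||% "derived", collapse = ",")
  cfg$k <- cfg$k %||% "scree"
  cfg$k_range <- paste(cfg$k_range, collapse = ",")
  w(data.frame(key = names(cfg), value = vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1))), "config.tsv")
  invisible(out_dir)
}
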