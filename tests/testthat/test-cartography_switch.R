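# helper: wrap an adjacency + membership into the package's containers
carto_inputs <- function(a, membership, values = NULL) {
  g <- adjacency_to_graph(a)
  comm <- structure(list(
    cluster_of = stats::setNames(as.integer(membership), rownames(a)),
    k = length(unique(membership))), class = "CommunityAssignment")
  if (is.null(values)) {
    set.seed(1)
    values <- matrix(rnorm(nrow(a) * 8), nrow = nrow(a),
                     dimnames = list(rownames(a), paste0("s", 1:8)))
  }
  list(graph = g, comm = comm, expr = make_expr(values))
}

test_that("within-module degree z-score matches hand arithmetic", {
  # community {a,b,c} with within-degrees (2,1,1): a-b, a-c edges
  a <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a["a", "b"] <- a["b", "a"] <- 1L
  a["a", "c"] <- a["c", "a"] <- 1L
  a["d", "a"] <- a["a", "d"] <- 1L          # d in its own community
  ci <- carto_inputs(a, c(1, 1, 1, 2))
  zg <- within_module_degree_z(ci$graph, ci$comm)
  sd_pop <- sqrt(mean((c(2, 1, 1) - 4 / 3)^2))
  expect_equal(zg[["a"]], (2 - 4 / 3) / sd_pop, tolerance = 1e-12)
  expect_equal(zg[["d"]], 0)                # singleton community convention

  # equal within-degree community: all zero
  ring <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  for (i in 1:4) { j <- i %% 4 + 1; ring[i, j] <- ring[j, i] <- 1L }
  ci2 <- carto_inputs(ring, rep(1, 4))
  expect_true(all(within_module_degree_z(ci2$graph, ci2$comm) == 0))
})

test_that("clusterphobic coefficient follows 1 - (k_in/k_tot)^2", {
  # node x: 2 internal links, 2 external -> 0.75
  a <- matrix(0L, 6, 6,
              dimnames = list(c("x", "i1", "i2", "e1", "e2", "f"),
                              c("x", "i1", "i2", "e1", "e2", "f")))
  for (v in c("i1", "i2", "e1", "e2")) a["x", v] <- a[v, "x"] <- 1L
  ci <- carto_inputs(a, c(1, 1, 1, 2, 2, 2))
  kpi <- clusterphobic_coefficient(ci$graph, ci$comm)
  expect_equal(kpi[["x"]], 0.75)
  expect_equal(kpi[["i1"]], 0)              # all links internal
  expect_equal(kpi[["e1"]], 1)              # all links external
  expect_equal(kpi[["f"]], 0)               # isolated convention
})

test_that("APCC equals the brute-force neighbour loop", {
  set.seed(67)
  a <- random_adjacency(12, 0.3)
  vals <- matrix(rnorm(12 * 10), nrow = 12,
                 dimnames = list(rownames(a), paste0("s", 1:10)))
  ci <- carto_inputs(a, rep(1, 12), vals)
  got <- apcc(ci$expr, ci$graph)
  ref <- bf_apcc(vals, a)
  expect_equal(got, ref, tolerance = 1e-12)

  # duplicate-profile neighbour gives exactly 1; negated gives -1
  v2 <- matrix(rnorm(10), nrow = 1)[rep(1, 3), ]
  v2[2, ] <- v2[1, ]
  v2[3, ] <- -v2[1, ]
  rownames(v2) <- c("n1", "n2", "n3")
  colnames(v2) <- paste0("s", 1:10)
  pairs <- matrix(0L, 3, 3, dimnames = list(rownames(v2), rownames(v2)))
  pairs["n1", "n2"] <- pairs["n2", "n1"] <- 1L
  ci2 <- carto_inputs(pairs, rep(1, 3), v2)
  ap <- apcc(ci2$expr, ci2$graph)
  expect_equal(ap[["n1"]], 1)
  expect_true(is.na(ap[["n3"]]))
  pairs["n1", "n3"] <- pairs["n3", "n1"] <- 1L
  ci3 <- carto_inputs(pairs, rep(1, 3), v2)
  expect_equal(apcc(ci3$expr, ci3$graph)[["n3"]], -1)
})

test_that("hub classes, regions and the switch rule use the stated cuts", {
  expect_true(switchnet:::is_switch_node(1.0, 0.9, -0.2))
  expect_false(switchnet:::is_switch_node(2.5, 0.9, -0.2))   # Zg boundary
  expect_false(switchnet:::is_switch_node(1.0, 0.8, -0.2))   # Kpi boundary
  expect_false(switchnet:::is_switch_node(1.0, 0.9, 0))      # APCC boundary
  expect_false(switchnet:::is_switch_node(1.0, 0.9, NA))

  # a crafted graph hits all three classes at once:
  # hub1 positively correlated with partners, fc negatively
  set.seed(71)
  base <- rnorm(12)
  vals <- rbind(hub_party = base,
                p1 = base + rnorm(12, sd = 0.05),
                p2 = base + rnorm(12, sd = 0.05),
                fc = -base + rnorm(12, sd = 0.05),
                dateish = rnorm(12))
  colnames(vals) <- paste0("s", 1:12)
  a <- matrix(0L, 5, 5, dimnames = list(rownames(vals), rownames(vals)))
  for (v in c("p1", "p2", "fc", "dateish"))
    a["hub_party", v] <- a[v, "hub_party"] <- 1L
  ci <- carto_inputs(a, c(1, 1, 1, 2, 2), vals)
  carto <- classify_nodes(ci$graph, ci$comm, ci$expr)
  cls <- stats::setNames(carto$hub_class, carto$node)
  expect_equal(cls[["p1"]], "party")        # r ~ 1 with its only neighbour
  expect_equal(cls[["fc"]], "fight_club")   # r ~ -1
  # "dateish" profile is uncorrelated noise: |APCC| small and non-negative
  # only asserted when it lands in [0, 0.5)
  if (carto$apcc[carto$node == "dateish"] >= 0)
    expect_equal(cls[["dateish"]], "date")

  # region assignment: low-Zg row splits at Kpi 0.05/0.62/0.8;
  # "fc" has every link outside its community (kpi = 1) and low Zg -> R4
  expect_equal(carto$region[carto$node == "fc"], "R4")
  expect_equal(carto$region[carto$node == "p1"], "R1")   # all-internal
})

test_that("cartography matches brute force on random graphs", {
  set.seed(73)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    a <- random_adjacency(n, runif(1, 0.05, 0.3))
    membership <- sample(1:4, n, replace = TRUE)
    ci <- carto_inputs(a, membership)
    ref <- bf_zg_kpi(a, membership)
    expect_equal(within_module_degree_z(ci$graph, ci$comm), ref$zg,
                 tolerance = 1e-12)
    expect_equal(clusterphobic_coefficient(ci$graph, ci$comm), ref$kpi,
                 tolerance = 1e-12)
    # kappa conservation: sum kappa = 2 * intra-community edge count
    el <- igraph::as_edgelist(ci$graph)
    intra <- sum(membership[match(el[, 1], rownames(a))] ==
                 membership[match(el[, 2], rownames(a))])
    expect_equal(sum(ref$kappa), 2 * intra)
  }
})

test_that("switch calls are always fight-club hubs with negative APCC", {
  sim <- generate_synthetic(synthetic_config(seed = 79))
  cfg <- run_config(fold_change = 1.5, correlation_threshold = 0.5,
                    seed = 79)
  res <- suppressMessages(run_pipeline(sim$expr, cfg))
  carto <- res$cartography
  sw <- carto$node[carto$is_switch]
  fc <- carto$node[carto$hub_class == "fight_club"]
  neg <- carto$node[!is.na(carto$apcc) & carto$apcc < 0]
  expect_true(all(sw %in% fc))
  expect_true(all(fc %in% neg))
  expect_equal(call_switch_genes(carto), sw)
})

test_that("biclustering orders switch genes into coherent blocks", {
  cfg <- synthetic_config(n_modules = 2, genes_per_module = 4, n_switch = 0,
                          n_noise_genes = 0, samples_per_group = 4,
                          loading = 1, noise_sd = 0.01, de_log2fc = 0,
                          seed = 83)
  sim <- generate_synthetic(cfg)
  genes <- rownames(sim$expr$values)
  bic <- bicluster_switch(sim$expr, genes)
  expect_setequal(bic$row_order, genes)
  expect_setequal(bic$col_order, colnames(sim$expr$values))
  # rows from the two modules form two clean blocks in the leaf order
  mods <- sim$truth$module_of[bic$row_order]
  expect_equal(sum(mods[-1] != mods[-length(mods)]), 1L)

  # identical rows merge first at height ~0
  m <- matrix(rnorm(3 * 6), nrow = 3,
              dimnames = list(c("r1", "r2", "r3"), NULL))
  m[2, ] <- m[1, ]
  exm <- make_expr(m)
  bic2 <- bicluster_switch(exm, rownames(m))
  expect_lt(bic2$linkage_rows$height[1], 1e-10)
  expect_setequal(abs(bic2$linkage_rows$merge[1, ]), c(1, 2))

  # permuting the input rows leaves merge heights unchanged
  bic3 <- bicluster_switch(exm, rev(rownames(m)))
  expect_equal(sort(bic3$linkage_rows$height),
               sort(bic2$linkage_rows$height), tolerance = 1e-12)

  expect_error(bicluster_switch(exm, "r1"), ">= 2 switch genes")
})
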