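make_collection <- function(...) {
  sets <- list(...)
  structure(lapply(sets, function(m) list(description = "d", members = m)),
            class = "GeneSetCollection")
}

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # background 10, set 5, query 4, overlap 4 -> C(5,4)C(5,0)/C(10,4) = 5/210
  bg <- paste0("g", 1:10)
  res <- enrich(paste0("g", 1:4), bg, make_collection(S = paste0("g", 1:5)))
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$overlap_count, 4L)

  # zero overlap reports p = 1 by convention
  res0 <- enrich(paste0("g", 6:9), bg, make_collection(S = paste0("g", 1:5)))
  expect_equal(res0$p_value, 1)

  # query = set = background: the outcome is certain
  resc <- enrich(bg, bg, make_collection(S = bg))
  expect_equal(resc$p_value, 1)

  # enumeration oracle for backgrounds <= 15
  set.seed(101)
  for (i in 1:20) {
    nb <- sample(8:15, 1)
    bg <- paste0("g", 1:nb)
    set <- sample(bg, sample(2:(nb - 1), 1))
    query <- sample(bg, sample(2:(nb - 1), 1))
    res <- enrich(query, bg, make_collection(S = set))
    ov <- length(intersect(set, query))
    ref <- if (ov == 0) 1 else
      bf_hyper_upper(ov, length(set), nb, length(query))
    expect_equal(res$p_value, ref, tolerance = 1e-12)
  }

  # q-values agree with the package's own BH on the p column
  coll <- make_collection(A = paste0("g", 1:3), B = paste0("g", 2:6),
                          C = paste0("g", 7:9), D = paste0("x", 1:4))
  bg <- paste0("g", 1:10)
  res <- enrich(paste0("g", 1:4), bg, coll)
  expect_equal(res$q_value, bh_fdr(res$p_value))
  expect_false("D" %in% res$set)            # no background overlap: skipped
  expect_error(enrich(character(0), bg, coll), "empty query")
  expect_error(enrich("zz", bg, coll), "not in background")
})

test_that("regulator ranking counts targets and routes through the star", {
  edges <- data.frame(regulator = "TF1", gene = paste0("sw", 1:4),
                      source = "db1")
  tab <- interaction_table(edges, "tf")
  rk <- rank_regulators(tab, paste0("sw", 1:4))
  expect_equal(rk$degree, 4L)
  expect_equal(rk$betweenness, 6)           # all 6 leaf pairs cross the hub

  # brute-force betweenness on random bipartite graphs
  set.seed(103)
  for (i in 1:5) {
    n_reg <- sample(3:6, 1); n_gene <- sample(4:10, 1)
    regs <- paste0("R", seq_len(n_reg)); genes <- paste0("G", seq_len(n_gene))
    pairs <- expand.grid(regulator = regs, gene = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    if (!nrow(pairs)) next
    pairs$source <- "s"
    rk <- suppressWarnings(
      rank_regulators(interaction_table(pairs, "tf"), genes))
    if (!nrow(rk)) next
    nodes <- c(paste0("reg:", sort(unique(pairs$regulator))),
               paste0("gene:", sort(unique(pairs$gene))))
    a <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(pairs))) {
      u <- paste0("reg:", pairs$regulator[r])
      v <- paste0("gene:", pairs$gene[r])
      a[u, v] <- a[v, u] <- 1L
    }
    ref <- bf_betweenness(a)
    for (r in rk$regulator)
      expect_equal(rk$betweenness[rk$regulator == r],
                   ref[[paste0("reg:", r)]], tolerance = 1e-9)
  }

  # source consensus: a 2-source regulator is dropped at min_sources = 3
  edges <- rbind(
    data.frame(regulator = "TF1", gene = "sw1",
               source = c("ENCODE", "ChEA", "JASPAR")),
    data.frame(regulator = "TF2", gene = "sw1",
               source = c("ENCODE", "ChEA")))
  rk <- rank_regulators(interaction_table(edges, "tf"), "sw1",
                        min_sources = 3)
  expect_equal(rk$regulator, "TF1")
  expect_equal(rk$n_sources, 3L)

  expect_warning(rank_regulators(interaction_table(
    data.frame(regulator = "TF1", gene = "other", source = "s"), "tf"),
    "sw1"), "no regulator")
})

test_that("overlap tables partition the union by shared-list count", {
  ov <- shared_between(list(l1 = c("A", "B"), l2 = c("B", "C")))
  expect_setequal(ov$items$item[ov$items$n_lists == 2], "B")
  expect_setequal(ov$items$item[ov$items$n_lists == 1], c("A", "C"))
  expect_equal(ov$summary$count[ov$summary$n == 2], 1L)

  # identical lists repeated n times: everything shared by n
  ident <- shared_between(list(a = c("x", "y"), b = c("x", "y"),
                               c = c("x", "y")))
  expect_true(all(ident$items$n_lists == 3))

  # counts over n partition the union
  set.seed(107)
  lists <- lapply(1:5, function(i) sample(paste0("g", 1:30),
                                          sample(5:20, 1)))
  names(lists) <- paste0("d", 1:5)
  ov <- shared_between(lists)
  expect_equal(sum(ov$summary$count), length(unique(unlist(lists))))
  expect_equal(nrow(ov$items), sum(ov$summary$count))

  expect_error(shared_between(list(a = "x")), "length")
})
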