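# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so they can certify them.

# random undirected simple graph as a 0/1 adjacency matrix
random_adjacency <- function(n, p = 0.2) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

adjacency_to_graph <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  class(g) <- c("CorrelationGraph", class(g))
  g
}

# all-pairs shortest paths by Floyd-Warshall
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# mean shortest path over reachable unordered pairs of the largest component
bf_asp <- function(a) {
  d <- bf_distances(a)
  comp <- bf_components(a)
  sizes <- table(comp)
  # same tie-break as the package documents: among equal-sized components,
  # the one holding the lexicographically smallest node name
  cands <- as.integer(names(sizes)[sizes == max(sizes)])
  min_name <- vapply(cands, function(k) min(rownames(a)[comp == k]),
                     character(1))
  main <- cands[order(min_name)][1L]
  idx <- which(comp == main)
  dd <- d[idx, idx][upper.tri(d[idx, idx])]
  mean(dd)
}

# connected components by flood fill
bf_components <- function(a) {
  n <- nrow(a)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] == 1))))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# unnormalised betweenness via shortest-path counting:
# sigma via DP on distances, then pair-by-pair dependency sums
bf_betweenness <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  sigma <- matrix(0, n, n)          # number of shortest s-t paths
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    reach <- which(is.finite(d[s, ]) & d[s, ] > 0)
    for (t in reach[order(d[s, reach])]) {
      if (d[s, t] == 1) { sigma[s, t] <- 1; next }
      preds <- which(a[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(d[s, t]) || d[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  stats::setNames(btw, rownames(a))
}

# within-module degree z-score and clusterphobic coefficient by direct loops
bf_zg_kpi <- function(a, membership) {
  n <- nrow(a)
  kappa <- k_tot <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k_tot[i] <- length(nb)
    kappa[i] <- sum(membership[nb] == membership[i])
  }
  zg <- numeric(n)
  for (c_id in unique(membership)) {
    idx <- which(membership == c_id)
    mu <- mean(kappa[idx])
    sdev <- sqrt(mean((kappa[idx] - mu)^2))
    zg[idx] <- if (sdev == 0) 0 else (kappa[idx] - mu) / sdev
  }
  kpi <- ifelse(k_tot == 0, 0, 1 - (kappa / k_tot)^2)
  list(zg = stats::setNames(zg, rownames(a)),
       kpi = stats::setNames(kpi, rownames(a)),
       kappa = stats::setNames(kappa, rownames(a)))
}

# APCC by an explicit loop over neighbours
bf_apcc <- function(values, a) {
  out <- stats::setNames(rep(NA_real_, nrow(a)), rownames(a))
  for (i in seq_len(nrow(a))) {
    nb <- which(a[i, ] == 1)
    if (!length(nb)) next
    rs <- vapply(nb, function(j)
      stats::cor(values[rownames(a)[i], ], values[rownames(a)[j], ]),
      numeric(1))
    out[i] <- mean(rs)
  }
  out
}

# Benjamini-Hochberg step-up by the textbook recipe
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# upper-tail hypergeometric P(X >= ov) by exhaustive enumeration of draws
bf_hyper_upper <- function(ov, set_size, background_size, query_size) {
  draws <- utils::combn(background_size, query_size)
  hits <- colSums(draws <= set_size)   # wlog successes are items 1..set_size
  mean(hits >= ov)
}

# expression fixture: tiny deterministic matrix with groups
make_expr <- function(values, n_case = NULL) {
  n <- ncol(values)
  if (is.null(n_case)) n_case <- n %/% 2
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(n))
  groups <- stats::setNames(
    rep(c("case", "control"), c(n_case, n - n_case)), colnames(values))
  expression_matrix(values, groups)
}
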