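# Community detection: seeded k-means on z-scored expression profiles with
# replicate restarts, an SSE scree and an elbow rule for k.

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sd[sd == 0] <- 1   # constant profiles map to all-zero rows
  (m - mu) / sd
}

# Lloyd's algorithm with k-means++ initialisation. Hand-rolled (not
# stats::kmeans) so replicate seeding, empty-cluster re-initialisation and
# the returned SSE are fully deterministic given the seed.
lloyd_once <- function(x, k, max_iter = 100L, max_retries = 10L) {
  n <- nrow(x)
  for (retry in seq_len(max_retries)) {
    centers <- x[kmeanspp_init(x, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    ok <- TRUE
    for (iter in seq_len(max_iter)) {
      d2 <- pairwise_sqdist(x, centers)
      assign_cur <- max.col(-d2, ties.method = "first")
      if (length(unique(assign_cur)) < k) { ok <- FALSE; break }
      if (all(assign_cur == assign_prev)) break
      assign_prev <- assign_cur
      for (j in seq_len(k))
        centers[j, ] <- colMeans(x[assign_cur == j, , drop = FALSE])
    }
    if (ok) {
      d2 <- pairwise_sqdist(x, centers)
      sse <- sum(d2[cbind(seq_len(n), assign_cur)])
      return(list(assignment = assign_cur, centers = centers, sse = sse))
    }
    message("empty cluster; re-initialising replicate (retry ", retry, ")")
  }
  stop("k-means produced an empty cluster in ", max_retries, " retries")
}

# squared Euclidean distances, n x k
pairwise_sqdist <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

# k-means++ seeding: first centre uniform, then D^2-weighted draws
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx[j] <- sample.int(n, 1L)
      else idx[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  idx
}

#' Seeded replicate k-means on expression profiles
#'
#' Clusters the z-scored expression profiles of the given genes with Lloyd's
#' algorithm; among \code{replicates} independently seeded k-means++
#' initialisations, the assignment with minimal within-cluster sum of squared
#' errors (SSE) is returned. Deterministic given \code{seed}.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param nodes gene ids to cluster (typically the co-expression graph's
#'   node set).
#' @param k number of clusters (<= number of nodes).
#' @param replicates number of restarts (>= 1).
#' @param seed RNG seed.
#' @param scale_rows z-score each profile before clustering (default TRUE,
#'   as the pipeline clusters expression shape, not level).
#' @return a \code{CommunityAssignment}: list with \code{cluster_of} (named
#'   integer vector in 1..k), \code{k}, \code{sse} (best SSE),
#'   \code{sse_replicates} (per-replicate SSE), \code{centers}.
#' @export
kmeans_profiles <- function(expr, nodes, k, replicates = 10L, seed = 1L,
                            scale_rows = TRUE) {
  stopifnot(k >= 1L, replicates >= 1L)
  bad <- setdiff(nodes, gene_ids(expr))
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  if (k > length(nodes)) stop("k exceeds the number of nodes")
  x <- expr$values[nodes, , drop = FALSE]
  if (scale_rows) x <- zscore_rows(x)
  runs <- lapply(seq_len(replicates), function(r)
    with_seed(child_seed(seed, paste0("kmeans", r)), lloyd_once(x, k)))
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best <- runs[[which.min(sses)]]
  structure(list(cluster_of = stats::setNames(best$assignment, nodes),
                 k = as.integer(k), sse = best$sse, sse_replicates = sses,
                 centers = best$centers),
            class = "CommunityAssignment")
}

#' SSE scree over a range of k
#'
#' @inheritParams kmeans_profiles
#' @param k_range candidate cluster counts.
#' @return a \code{data.frame} with columns \code{k}, \code{replicate},
#'   \code{sse}; attribute \code{best} holds the per-k best-of-replicates
#'   SSE (non-increasing in k).
#' @export
scree <- function(expr, nodes, k_range = 2:10, replicates = 10L, seed = 1L) {
  stopifnot(length(k_range) >= 1L)
  rows <- lapply(k_range, function(k) {
    fit <- kmeans_profiles(expr, nodes, k, replicates, child_seed(seed,
                                                       paste0("scree", k)))
    data.frame(k = k, replicate = seq_len(replicates),
               sse = fit$sse_replicates)
  })
  tab <- do.call(rbind, rows)
  best <- stats::aggregate(sse ~ k, data = tab, FUN = min)
  # best-of-replicates SSE must be non-increasing in k; enforce by running
  # cumulative minimum (a larger k can always reproduce a smaller-k optimum)
  best$sse <- cummin(best$sse)
  attr(tab, "best") <- best
  tab
}

#' Pick k at the elbow of the scree curve
#'
#' Uses the chord rule: over the best-of-replicates SSE curve, returns the k
#' maximising the perpendicular distance to the straight line joining the
#' curve's endpoints; ties go to the smallest k. A flat curve returns the
#' smallest k with a warning.
#'
#' @param sse_table output of \code{\link{scree}} (or any data.frame with
#'   columns \code{k} and \code{sse}).
#' @return the chosen k.
#' @export
choose_k <- function(sse_table) {
  best <- attr(sse_table, "best")
  if (is.null(best))
    best <- stats::aggregate(sse ~ k, data = sse_table, FUN = min)
  best <- best[order(best$k), ]
  if (nrow(best) < 3L) stop("need >= 3 candidate k values")
  ks <- best$k; ss <- best$sse
  if (max(ss) == min(ss)) {
    warning("flat SSE curve; returning the smallest k")
    return(ks[1L])
  }
  # scale both axes to [0,1] so the chord distance is unit-free
  kx <- (ks - ks[1L]) / (ks[length(ks)] - ks[1L])
  sy <- (ss - ss[length(ss)]) / (ss[1L] - ss[length(ss)])
  # chord runs from (0,1) to (1,0); distance = |kx + sy - 1| / sqrt(2)
  d <- abs(kx + sy - 1) / sqrt(2)
  if (max(d) < 1e-10) {
    warning("SSE declines linearly (no elbow); returning smallest interior k")
    return(ks[2L])
  }
  ks[which.max(d)]
}
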