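#' Remove unexpressed genes
#'
#' A gene is kept when at least \code{min_fraction_expressed} of its samples
#' have log2 expression >= \code{min_mean}. Gene order is preserved.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param min_mean expression level (log2 units) counting as "expressed".
#' @param min_fraction_expressed required fraction of samples at or above
#'   \code{min_mean}; 0 disables the filter.
#' @return the filtered \code{ExpressionMatrix}.
#' @export
preprocess <- function(expr, min_mean = 1, min_fraction_expressed = 0.5) {
  stopifnot(min_mean >= 0, min_fraction_expressed >= 0,
            min_fraction_expressed <= 1)
  frac <- rowMeans(expr$values >= min_mean)
  keep <- frac >= min_fraction_expressed
  if (!any(keep))
    stop("no gene passes the expression filter; lower min_mean or ",
         "min_fraction_expressed")
  subset_expression(expr, genes = gene_ids(expr)[keep])
}

#' Per-gene log2 fold change (case minus control)
#'
#' @param expr log2-scale \code{ExpressionMatrix} with both groups present.
#' @return named numeric vector: mean over case samples minus mean over
#'   control samples, per gene.
#' @export
log2_fold_changes <- function(expr) {
  cs <- case_ids(expr); ct <- control_ids(expr)
  if (length(cs) < 1L || length(ct) < 1L)
    stop("both groups must have at least one sample")
  rowMeans(expr$values[, cs, drop = FALSE]) -
    rowMeans(expr$values[, ct, drop = FALSE])
}

#' Per-gene Welch t-test p-values
#'
#' Two-sided unequal-variance t-test of case vs control per gene, vectorised
#' over genes. When both groups have zero variance the p-value is 1 for equal
#' means and 0 otherwise.
#'
#' @param expr an \code{ExpressionMatrix} with >= 2 samples per group.
#' @return named numeric vector of p-values in [0, 1].
#' @export
welch_p_values <- function(expr) {
  check_group_sizes(expr, 2L)
  x <- expr$values[, case_ids(expr), drop = FALSE]
  y <- expr$values[, control_ids(expr), drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  se2 <- vx / nx + vy / ny
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 1, 0)
  p
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return step-up adjusted values, clipped to [0, 1], monotone in p.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Full differential-expression table
#'
#' @param expr an \code{ExpressionMatrix} (after \code{\link{preprocess}}).
#' @param fold_change linear fold-change threshold (> 1); a gene is retained
#'   when |log2fc| >= log2(fold_change) and q <= alpha.
#' @param alpha FDR level; \code{alpha = 1} disables the significance test
#'   (pure fold-change ranking).
#' @return a \code{DifferentialResult} data.frame: gene, mean_case,
#'   mean_control, log2fc, p_value, q_value, retained.
#' @export
differential_table <- function(expr, fold_change = 2, alpha = 0.05) {
  stopifnot(fold_change > 1, alpha > 0, alpha <= 1)
  fc <- log2_fold_changes(expr)
  p <- welch_p_values(expr)
  q <- bh_fdr(p)
  res <- data.frame(
    gene = gene_ids(expr),
    mean_case = rowMeans(expr$values[, case_ids(expr), drop = FALSE]),
    mean_control = rowMeans(expr$values[, control_ids(expr), drop = FALSE]),
    log2fc = unname(fc), p_value = unname(p), q_value = unname(q),
    stringsAsFactors = FALSE, row.names = NULL)
  res$retained <- abs(res$log2fc) >= log2(fold_change) & res$q_value <= alpha
  class(res) <- c("DifferentialResult", "data.frame")
  attr(res, "fold_change") <- fold_change
  attr(res, "alpha") <- alpha
  res
}

#' Retained gene set from a differential table
#'
#' @param diff a \code{DifferentialResult} (from
#'   \code{\link{differential_table}}).
#' @param fold_change,alpha thresholds; defaults re-use those stored on
#'   \code{diff}.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(diff, fold_change = attr(diff, "fold_change"),
                         alpha = attr(diff, "alpha")) {
  stopifnot(inherits(diff, "DifferentialResult"),
            fold_change > 1, alpha > 0, alpha <= 1)
  keep <- abs(diff$log2fc) >= log2(fold_change) & diff$q_value <= alpha
  diff$gene[keep]
}
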