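#' Expression matrix with case/control design
#'
#' The universal input container of the pipeline: a genes x samples matrix of
#' expression values on log2 scale, plus a group label (\code{"case"} or
#' \code{"control"}) per sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be finite.
#' @param groups named character vector mapping every sample id to
#'   \code{"case"} or \code{"control"}.
#' @param scale either \code{"log2"} or \code{"linear"}. Linear values are
#'   transformed with \code{log2(x + 1)} on construction, so a stored object
#'   is always on log2 scale.
#'
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values} (log2 matrix), \code{groups} (named character vector in
#'   column order) and \code{scale} (always \code{"log2"} after construction).
#' @export
expression_matrix <- function(values, groups, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("sample(s) without group label: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(groups), sample_ids)
  if (length(extra))
    stop("unknown sample(s) in annotation: ", paste(extra, collapse = ", "))
  groups <- groups[sample_ids]
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (scale == "linear") {
    if (any(values < 0)) stop("linear-scale values must be non-negative")
    values <- log2(values + 1)
  }
  structure(list(values = values, groups = groups, scale = "log2"),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d case, %d control), %s scale\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control"), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

case_ids <- function(expr) names(expr$groups)[expr$groups == "case"]
control_ids <- function(expr) names(expr$groups)[expr$groups == "control"]

check_group_sizes <- function(expr, min_n = 2L) {
  n_case <- length(case_ids(expr)); n_ctl <- length(control_ids(expr))
  if (n_case < min_n || n_ctl < min_n)
    stop(sprintf("need >= %d samples per group (have %d case, %d control)",
                 min_n, n_case, n_ctl))
  invisible(TRUE)
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param genes character vector of gene ids to keep (default: all).
#' @param samples character vector of sample ids to keep (default: all).
#' @return the subsetted \code{ExpressionMatrix}; original order preserved.
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  g <- genes %||% gene_ids(expr)
  s <- samples %||% sample_ids(expr)
  bad <- setdiff(g, gene_ids(expr))
  if (length(bad)) stop("unknown gene id(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(s, sample_ids(expr))
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  g <- gene_ids(expr)[gene_ids(expr) %in% g]
  s <- sample_ids(expr)[sample_ids(expr) %in% s]
  expression_matrix(expr$values[g, s, drop = FALSE], expr$groups[s])
}

#' Collapse duplicate-feature rows to one row per gene
#'
#' Helper for probe-level inputs: among rows mapping to the same gene, keeps
#' the row with the highest mean expression. Identifier mapping itself is the
#' caller's job; this only resolves a many-rows-per-gene table.
#'
#' @param values numeric matrix with (possibly duplicated) rownames.
#' @return matrix with unique rownames, max-mean row retained per id.
#' @export
collapse_max_mean <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  means <- rowMeans(values)
  ord <- order(rownames(values), -means)
  v <- values[ord, , drop = FALSE]
  v[!duplicated(rownames(v)), , drop = FALSE]
}
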