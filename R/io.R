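#' Read an expression matrix and its sample annotation
#'
#' The matrix file is a delimited table with gene ids in the first column and
#' sample ids in the header; the annotation file has two columns, sample id
#' and group (\code{case}/\code{control}). Delimiter is auto-detected between
#' tab and comma from the header, overridable via \code{sep}.
#'
#' The expression scale is auto-detected unless given: values are taken as
#' log2 when the matrix maximum is below 30, otherwise as linear and
#' log2(x+1)-transformed on load.
#'
#' @param matrix_path path to the expression table.
#' @param annotation_path path to the 2-column sample annotation.
#' @param sep field delimiter; \code{NULL} (default) auto-detects.
#' @param scale \code{"auto"} (default), \code{"log2"} or \code{"linear"}.
#' @return an \code{\link{expression_matrix}} with sample order as in the
#'   matrix header.
#' @export
read_expression <- function(matrix_path, annotation_path, sep = NULL,
                            scale = c("auto", "log2", "linear")) {
  scale <- match.arg(scale)
  msep <- detect_sep(matrix_path, sep)
  tab <- utils::read.table(matrix_path, sep = msep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"")
  if (ncol(tab) < 2L) stop("expression table needs gene id column + samples")
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 ids[bad[["row"]]], colnames(vals)[bad[["col"]]]))
  }
  rownames(num) <- ids
  asep <- detect_sep(annotation_path, sep)
  ann <- utils::read.table(annotation_path, sep = asep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) stop("annotation needs columns: sample_id, group")
  groups <- stats::setNames(as.character(ann[[2L]]), as.character(ann[[1L]]))
  if (scale == "auto") scale <- if (max(num) < 30) "log2" else "linear"
  expression_matrix(num, groups, scale = scale)
}

#' Write an expression matrix and annotation to delimited text
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param matrix_path,annotation_path output paths.
#' @param sep delimiter (default tab).
#' @return invisibly, the two paths.
#' @export
write_expression <- function(expr, matrix_path, annotation_path, sep = "\t") {
  tab <- data.frame(gene_id = gene_ids(expr), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample_id = sample_ids(expr),
                    group = unname(expr$groups))
  utils::write.table(ann, annotation_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' Duplicate members within a line are collapsed.
#'
#' @param path path to the GMT file.
#' @return a \code{GeneSetCollection}: a named list of sets, each a list with
#'   \code{description} and \code{members}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need >= 3", i, length(f)))
    name <- f[[1L]]
    if (name %in% names(sets))
      stop(sprintf("duplicate set name '%s' at GMT line %d", name, i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("empty member list at GMT line %d", i))
    sets[[name]] <- list(description = f[[2L]], members = members)
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a gene-set collection in GMT format
#' @param collection a \code{GeneSetCollection} (see \code{\link{read_gmt}}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulator-gene edge table
#'
#' Delimited table with columns \code{regulator} and \code{gene}, plus an
#' optional \code{source} column (defaults to \code{"user"}). Duplicated
#' (regulator, gene, source) triples are collapsed with a warning.
#'
#' @param path path to the table.
#' @param kind one of \code{"tf"}, \code{"mirna"}, \code{"chemical"}.
#' @param sep delimiter; \code{NULL} auto-detects.
#' @return an \code{InteractionTable}: data.frame of edges with attribute
#'   \code{kind}.
#' @export
read_edge_table <- function(path, kind = c("tf", "mirna", "chemical"),
                            sep = NULL) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, sep = detect_sep(path, sep), header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("regulator", "gene")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("edge table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$source)) tab$source <- "user"
  if (any(!nzchar(tab$source))) stop("empty source tag in edge table")
  edges <- tab[, c("regulator", "gene", "source")]
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sum(dup), " duplicated edge triple(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  interaction_table(edges, kind)
}

#' Construct an InteractionTable from an edge data.frame
#' @param edges data.frame with columns regulator, gene, source.
#' @param kind one of \code{"tf"}, \code{"mirna"}, \code{"chemical"}.
#' @return the validated \code{InteractionTable}.
#' @export
interaction_table <- function(edges, kind = c("tf", "mirna", "chemical")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(edges),
            all(c("regulator", "gene", "source") %in% names(edges)))
  if (anyDuplicated(edges[, c("regulator", "gene", "source")]))
    stop("duplicate (regulator, gene, source) triple")
  structure(edges, class = c("InteractionTable", "data.frame"), kind = kind)
}

#' Write an InteractionTable to delimited text
#' @param table an \code{InteractionTable}.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @return invisibly, \code{path}.
#' @export
write_edge_table <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a one-id-per-line gene list
#' @param path file path.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector of ids to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
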