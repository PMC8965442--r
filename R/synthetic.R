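#' Configuration for the synthetic expression generator
#'
#' Defaults are the strong-signal benchmark: 4 modules of 25 genes, 5 switch
#' genes, 10 case + 10 control samples, factor loading 0.9, noise sd 0.3 and
#' a 1.5 log2-unit case shift on all structured genes.
#'
#' @param n_modules number of planted co-expression modules (>= 1).
#' @param genes_per_module genes in each module (>= 1).
#' @param n_switch number of planted switch genes; each loads negatively on
#'   \code{modules_per_switch} module factors, so it is anti-correlated with
#'   the members of the modules it touches.
#' @param n_noise_genes unstructured background genes (>= 0).
#' @param samples_per_group samples in each of case/control (>= 3).
#' @param loading module-factor loading strength in (0, 1].
#' @param noise_sd independent per-gene noise sd (> 0 allowed to be tiny).
#' @param de_log2fc case-vs-control shift (log2 units). Module members shift
#'   by +de_log2fc; switch genes shift by -de_log2fc, mirroring their
#'   negative factor loadings, so their anti-correlation with module members
#'   survives pooled-sample correlation (a same-sign shift would add
#'   +de_log2fc^2/4 to every between-gene covariance and mask it). Noise
#'   genes never shift.
#' @param modules_per_switch modules each switch gene spans (default 2).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return a \code{SyntheticConfig} list.
#' @export
synthetic_config <- function(n_modules = 4L, genes_per_module = 25L,
                             n_switch = 5L, n_noise_genes = 50L,
                             samples_per_group = 10L, loading = 0.9,
                             noise_sd = 0.3, de_log2fc = 1.5,
                             modules_per_switch = 2L, seed = 1L) {
  cfg <- list(n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              n_switch = as.integer(n_switch),
              n_noise_genes = as.integer(n_noise_genes),
              samples_per_group = as.integer(samples_per_group),
              loading = loading, noise_sd = noise_sd,
              de_log2fc = de_log2fc,
              modules_per_switch = as.integer(modules_per_switch),
              seed = as.integer(seed))
  stopifnot(cfg$n_modules >= 1L, cfg$genes_per_module >= 1L,
            cfg$n_switch >= 0L, cfg$n_noise_genes >= 0L,
            cfg$samples_per_group >= 3L,
            cfg$loading > 0, cfg$loading <= 1, cfg$noise_sd >= 0,
            cfg$modules_per_switch >= 1L)
  if (cfg$n_switch > 0L && cfg$modules_per_switch > 1L && cfg$n_modules < 2L)
    stop("a switch gene must span >= 2 modules; need n_modules >= 2")
  if (cfg$modules_per_switch > cfg$n_modules)
    stop("modules_per_switch cannot exceed n_modules")
  structure(cfg, class = "SyntheticConfig")
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' Per sample, each module m has a latent factor f_m ~ N(0, 1). A member of
#' module m is \code{baseline + loading*f_m + noise_sd*eps} (+ de_log2fc for
#' case samples). A switch gene spanning modules A, B, ... is
#' \code{baseline - loading*mean(f_A, f_B, ...) + noise_sd*eps}
#' (- de_log2fc for cases), hence negatively correlated with the members of
#' the modules it touches in both the factor structure and the group effect.
#' Noise genes are \code{baseline + noise_sd*eps} with no group shift, so in
#' the low-noise limit the differential filter retains exactly the
#' structured genes. Baselines are drawn once per gene from U(5, 10) so
#' values resemble log2 microarray intensities.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{expr} (an \code{ExpressionMatrix}) and
#'   \code{truth} (a \code{SyntheticTruth}: \code{module_of} named vector
#'   with labels \code{M1..Mk}, \code{switch}, \code{noise};
#'   \code{switch_genes}; \code{de_genes}; \code{switch_modules} list of the
#'   module indices each switch gene spans).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  c(n_modules, genes_per_module, n_switch, n_noise_genes, samples_per_group,
    loading, noise_sd, de_log2fc, modules_per_switch, seed) %<-% config

  with_seed(seed, {
    n_samples <- 2L * samples_per_group
    sample_id <- c(sprintf("case_%02d", seq_len(samples_per_group)),
                   sprintf("ctrl_%02d", seq_len(samples_per_group)))
    groups <- stats::setNames(rep(c("case", "control"),
                                  each = samples_per_group), sample_id)
    is_case <- groups == "case"

    member_ids <- unlist(lapply(seq_len(n_modules), function(m)
      sprintf("M%d_G%02d", m, seq_len(genes_per_module))))
    switch_ids <- if (n_switch > 0L) sprintf("SW%02d", seq_len(n_switch))
                  else character(0)
    noise_ids <- if (n_noise_genes > 0L) sprintf("NOISE%03d",
                                                 seq_len(n_noise_genes))
                 else character(0)
    ids <- c(member_ids, switch_ids, noise_ids)
    n_genes <- length(ids)

    factors <- matrix(stats::rnorm(n_modules * n_samples),
                      nrow = n_modules)   # module x sample latent factors
    baseline <- stats::runif(n_genes, 5, 10)
    vals <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   nrow = n_genes, dimnames = list(ids, sample_id))

    module_of_member <- rep(seq_len(n_modules), each = genes_per_module)
    vals[member_ids, ] <- vals[member_ids, , drop = FALSE] +
      loading * factors[module_of_member, , drop = FALSE]

    switch_modules <- lapply(seq_len(n_switch), function(i)
      sort(sample.int(n_modules, modules_per_switch)))
    for (i in seq_len(n_switch)) {
      f_mean <- colMeans(factors[switch_modules[[i]], , drop = FALSE])
      vals[switch_ids[[i]], ] <- vals[switch_ids[[i]], ] - loading * f_mean
    }

    structured <- c(member_ids, switch_ids)
    vals[member_ids, is_case] <- vals[member_ids, is_case] + de_log2fc
    if (n_switch > 0L)
      vals[switch_ids, is_case] <- vals[switch_ids, is_case] - de_log2fc
    vals <- vals + baseline

    module_of <- stats::setNames(
      c(sprintf("M%d", module_of_member),
        rep("switch", n_switch), rep("noise", n_noise_genes)), ids)
    truth <- structure(
      list(module_of = module_of,
           switch_genes = switch_ids,
           de_genes = if (de_log2fc != 0) structured else character(0),
           switch_modules = stats::setNames(switch_modules, switch_ids)),
      class = "SyntheticTruth")
    list(expr = expression_matrix(vals, groups), truth = truth,
         config = config)
  })
}

# tiny destructuring helper for config lists
`%<-%` <- function(lhs, rhs) {
  vars <- as.character(as.list(substitute(lhs))[-1L])
  for (v in vars) assign(v, rhs[[v]], envir = parent.frame())
  invisible(NULL)
}

#' Histogram of per-gene log2 fold changes
#'
#' @param expr an \code{ExpressionMatrix} with both groups present.
#' @param bins number of histogram bins.
#' @return list with \code{breaks}, \code{counts}, \code{mids},
#'   \code{log2fc} (the per-gene values); counts sum to the gene count.
#' @export
fold_change_histogram <- function(expr, bins = 30L) {
  fc <- log2_fold_changes(expr)
  h <- graphics::hist(fc, breaks = bins, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids, log2fc = fc)
}

#' Write a synthetic data set (matrix, annotation, truth) to files
#'
#' @param sim result of \code{\link{generate_synthetic}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(sim$expr, paths[["matrix"]], paths[["annotation"]])
  truth <- data.frame(gene = names(sim$truth$module_of),
                      label = unname(sim$truth$module_of))
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
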