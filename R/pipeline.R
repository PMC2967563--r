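#' Assemble a pipeline configuration
#'
#' Collects every option of the full analysis (compliance check ->
#' optional augmentation -> iterative trimming -> permutation test) in
#' one validated list. All stochastic stages derive their RNG streams
#' from the single top-level `seed`.
#'
#' @param expression expression matrix or path to a TSV file.
#' @param network `nca_pattern`, edge data.frame, or path to a TSV file.
#' @param pool optional genome-wide expression pool (matrix or path) for
#'   the permutation null; defaults to the analysed data with a logged
#'   caveat.
#' @param out_dir optional output directory; when given, all
#'   intermediates plus a JSON run manifest are written.
#' @param seed top-level integer seed.
#' @param lambda,tol,max_iter solver settings (see [nca_options()]).
#' @param stop_retention trimming stop threshold.
#' @param augment allow in-silico augmentation when the data are
#'   under-determined.
#' @param n_replicates optional override of the augmentation replicate
#'   count.
#' @param n_null number of permutation null datasets.
#' @param alpha significance level for TF calls.
#' @param call_mode `"raw"` or `"adjusted"` p-values for the
#'   significance flag.
#' @return A list of class `nca_config`.
#' @export
run_config <- function(expression, network, pool = NULL, out_dir = NULL,
                       seed = 1L, lambda = 0.1, tol = 1e-6,
                       max_iter = 500L, stop_retention = 0.99,
                       augment = TRUE, n_replicates = NULL,
                       n_null = 270L, alpha = 0.1, call_mode = "raw") {
  structure(list(expression = expression, network = network, pool = pool,
                 out_dir = out_dir, seed = as.integer(seed),
                 options = nca_options(lambda = lambda, tol = tol,
                                       max_iter = max_iter),
                 stop_retention = stop_retention, augment = augment,
                 n_replicates = n_replicates, n_null = as.integer(n_null),
                 alpha = alpha, call_mode = call_mode),
            class = "nca_config")
}

#' Run the full trimming-and-permutation pipeline
#'
#' Executes, with stage-tagged logging: load/validate inputs ->
#' compliance check -> in-silico augmentation if the data are
#' under-determined (and `augment` is enabled; otherwise a documented
#' error) -> iterative network trimming -> genome-scramble null
#' ensemble -> perturbed-TF calls. When `out_dir` is set, the trimmed
#' edge list, per-iteration summary, A/P matrices, TF calls and a JSON
#' manifest (options, seeds, iteration counts, edge counts) are written.
#'
#' @param config an `nca_config` from [run_config()].
#' @return A list with `expression` (as analysed, possibly augmented),
#'   `pattern0`, `compliance`, `trace` (`nca_trim`), `nulls`, `calls`
#'   and `manifest`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nca_config"))
  seed <- config$seed

  E <- config$expression
  if (is.character(E)) E <- read_expression(E)
  else E <- expression_matrix(E)

  net <- config$network
  pattern0 <- if (inherits(net, "nca_pattern")) net
    else if (is.data.frame(net)) pattern_from_edges(net, rownames(E))
    else read_network(net, rownames(E))
  E <- E[rownames(pattern0$mask), , drop = FALSE]
  nca_log("load", "%d genes x %d experiments, %d TFs, %d edges",
          nrow(E), ncol(E), ncol(pattern0$mask), n_edges(pattern0))

  pool <- config$pool
  if (is.null(pool)) {
    nca_log("nulls", "no genome-wide pool supplied; using the analysed data as the scramble pool")
    pool <- E
  } else if (is.character(pool)) pool <- read_expression(pool)

  comp <- check_compliance(pattern0, ncol(E))
  plan <- augmentation_plan(E, pattern0, config$n_replicates)
  E_analysed <- E
  pool_analysed <- pool
  if (plan$needed) {
    if (!config$augment)
      stop("data are under-determined (criterion (iii) violated or M < 4) and augmentation is disabled; ",
           "enable augmentation or supply more experiments")
    nca_log("augment", "augmenting %d -> %d columns (%d replicate blocks, sigma2 = %.4g)",
            ncol(E), ncol(E) * (1L + plan$n_replicates), plan$n_replicates,
            plan$sigma2)
    E_analysed <- augment_expression(E, plan$n_replicates,
                                     seed = derive_seed(seed, "augment"))
    pool_analysed <- augment_expression(pool, plan$n_replicates,
                                        seed = derive_seed(seed, "augment-pool"))
  }

  trace <- trim_network(E_analysed, pattern0,
                        stop_retention = config$stop_retention,
                        seed = derive_seed(seed, "trim"),
                        options = config$options)

  nulls <- build_nulls(pool_analysed, trace$final_pattern,
                       trace$final_decomposition, n = config$n_null,
                       seed = derive_seed(seed, "nulls"),
                       options = config$options)
  calls <- call_perturbed(trace$final_decomposition, nulls,
                          alpha = config$alpha, mode = config$call_mode)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ncatrim")),
    seed = seed,
    options = unclass(config$options),
    stop_retention = config$stop_retention,
    augmented = plan$needed,
    n_replicates = if (plan$needed) plan$n_replicates else 0L,
    sigma2 = plan$sigma2,
    compliance = list(criterion1_ok = comp$criterion1_ok,
                      criterion2_ok = comp$criterion2_ok,
                      criterion3_ok = comp$criterion3_ok),
    n_iterations = trace$n_iterations,
    edge_counts = trace$edge_counts,
    retained_fraction = trace$retained_fraction,
    n_null = config$n_null,
    n_null_failed = nulls$n_failed,
    alpha = config$alpha,
    n_significant = sum(calls$summary$significant))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_edges(trace$final_pattern, file.path(config$out_dir, "edges_final.tsv"))
    utils::write.table(
      data.frame(iteration = seq_along(trace$retained_fraction),
                 edges = trace$edge_counts[-1],
                 retained_fraction = trace$retained_fraction),
      file.path(config$out_dir, "iterations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_decomposition(trace$final_decomposition, config$out_dir)
    utils::write.table(calls$summary, file.path(config$out_dir, "tf_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(expression = E_analysed, pattern0 = pattern0,
                 compliance = comp, trace = trace, nulls = nulls,
                 calls = calls, manifest = manifest))
}
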