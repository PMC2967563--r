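#' Small-sample corrected Akaike information criterion
#'
#' For a per-gene linear model with k regulators fitted to M expression
#' measurements, with the error variance estimated by maximum likelihood
#' as RSS / M:
#'
#'   AICc = M * log(2 * pi * RSS / M) + M * (M + k) / (M - k - 2)
#'
#' (natural logarithm). The second term penalises model size and blows up
#' as k approaches M - 2, which is what lets forward selection stop
#' without any user-supplied threshold. A perfect fit (RSS = 0) returns
#' `-Inf`, so it dominates every comparison.
#'
#' @param rss residual sum of squares of the fitted model.
#' @param M number of expression measurements.
#' @param k number of regulators in the model.
#' @return The AICc value (scalar).
#' @examples
#' aicc(12, M = 12, k = 1)  # 12*log(2*pi) + 12*13/9
#' @export
aicc <- function(rss, M, k) {
  if (M - k - 2 <= 0) stop("model too large for AICc: need M - k - 2 > 0")
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) return(-Inf)
  M * log(2 * pi * rss / M) + M * (M + k) / (M - k - 2)
}

#' Forward stepwise selection of a gene's regulators
#'
#' Greedy forward search over a gene's candidate regulators using their
#' estimated TFA profiles as explanatory variables. At each step every
#' remaining candidate is tried, all coefficients are refit jointly by
#' ordinary least squares (no intercept; the data are log-ratios), and
#' the model with the smallest RSS is kept; ties are broken by candidate
#' order. The search stops when the AICc of the best k-regulator model is
#' not smaller than that of the (k-1)-regulator model, when candidates
#' are exhausted, or at the ceiling k = M - 3 that keeps the AICc
#' denominator positive. The first regulator is always accepted, so no
#' gene is left without a regulator.
#'
#' @param e_i numeric expression vector of one gene (length M).
#' @param P TFA matrix with TF ids as rownames (rows cover `candidates`).
#' @param candidates character vector of candidate TF ids.
#' @param gene_id optional gene label carried into the result.
#' @return A list with `gene_id`, `selected_tfs` (in selection order),
#'   `coefficients` (named, from the final joint refit), `rss_path`,
#'   `aicc_path` and `stopped_at_k`.
#' @export
stepwise_select <- function(e_i, P, candidates, gene_id = NULL) {
  M <- length(e_i)
  if (M < 4L)
    stop("model too large for AICc: need at least 4 measurements (M - k - 2 > 0 at k = 1); augment the data first")
  if (length(candidates) == 0L) stop("candidate set is empty")
  missing_tf <- setdiff(candidates, rownames(P))
  if (length(missing_tf))
    stop("TFA rows missing for candidate(s): ", paste(missing_tf, collapse = ", "))

  k_max <- min(length(candidates), M - 3L)
  # residuals at double-precision rounding level relative to the signal
  # are an exact fit for model-scoring purposes; without this floor the
  # log-RSS term keeps "improving" on numerical noise and the search
  # overfits
  rss_floor <- sum(e_i^2) * .Machine$double.eps
  selected <- character(0)
  coefs <- numeric(0)
  rss_path <- numeric(0)
  aicc_path <- numeric(0)
  prev_aicc <- Inf
  remaining <- candidates

  while (length(remaining) > 0L && length(selected) < k_max) {
    best_rss <- Inf; best_tf <- NULL; best_coef <- NULL
    for (tf in remaining) {
      X <- t(P[c(selected, tf), , drop = FALSE])
      fit <- stats::lm.fit(X, e_i)
      rss <- sum(fit$residuals^2)
      if (is.finite(rss) && rss < best_rss) {
        best_rss <- rss; best_tf <- tf; best_coef <- fit$coefficients
      }
    }
    if (is.null(best_tf)) {  # every fit degenerate (non-finite RSS)
      best_tf <- remaining[1]
      best_coef <- stats::setNames(rep(0, length(selected) + 1),
                                   c(selected, best_tf))
      best_rss <- sum(e_i^2)
      nca_warn("stepwise", "all candidate fits singular for gene %s; retaining %s",
               gene_id %||% "?", best_tf)
    }
    new_aicc <- aicc(if (best_rss <= rss_floor) 0 else best_rss,
                     M, length(selected) + 1L)
    if (new_aicc >= prev_aicc) break
    selected <- c(selected, best_tf)
    remaining <- setdiff(remaining, best_tf)
    rss_path <- c(rss_path, best_rss)
    aicc_path <- c(aicc_path, new_aicc)
    prev_aicc <- new_aicc
    coefs <- best_coef
  }

  if (anyNA(coefs)) coefs[is.na(coefs)] <- 0
  names(coefs) <- selected
  list(gene_id = gene_id, selected_tfs = selected, coefficients = coefs,
       rss_path = rss_path, aicc_path = aicc_path,
       stopped_at_k = length(selected))
}

#' One trimming pass over every gene
#'
#' Applies [stepwise_select()] to every gene, using the TFA profiles of a
#' decomposition computed from the current pattern, and returns the
#' pattern whose row i keeps exactly the selected regulators of gene i.
#' TFs whose regulon empties are dropped from the pattern with a warning,
#' since a TF without target genes cannot be estimated in the next
#' decomposition.
#'
#' @param E expression matrix aligned with `pattern`.
#' @param pattern current `nca_pattern`.
#' @param dec `nca_decomposition` computed from `pattern` (supplies the
#'   TFA explanatory variables).
#' @return A new `nca_pattern` with its iteration counter incremented.
#' @export
trim_iteration <- function(E, pattern, dec) {
  stopifnot(inherits(pattern, "nca_pattern"), inherits(dec, "nca_decomposition"))
  Z <- pattern$mask
  if (!identical(rownames(E), rownames(Z)))
    stop("gene sets of E and the pattern must be identical and identically ordered")
  tf_ids <- colnames(Z)
  newZ <- matrix(0, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  for (i in seq_len(nrow(Z))) {
    cand <- tf_ids[Z[i, ] > 0]
    sel <- stepwise_select(E[i, ], dec$P, cand, gene_id = rownames(Z)[i])
    newZ[i, sel$selected_tfs] <- 1
  }
  emptied <- colSums(newZ) == 0
  if (any(emptied)) {
    nca_warn("trim", "dropping TF(s) with emptied regulon: %s",
             paste(tf_ids[emptied], collapse = ", "))
    newZ <- newZ[, !emptied, drop = FALSE]
  }
  connectivity_pattern(newZ, iteration = pattern$iteration + 1L)
}

#' Iterative network trimming
#'
#' Alternates constrained decomposition with per-gene forward stepwise
#' selection: TFAs estimated from the current connectivity feed the
#' per-gene regressions, weak edges are removed, and the loop repeats
#' until an iteration retains more than `stop_retention` of its input
#' edges (default 99%). The final decomposition is recomputed on the
#' final pattern.
#'
#' The data must be determined enough for the stepwise step: at least 4
#' experiments and no gene with more regulators than experiments
#' (compliance criterion iii). Under-determined inputs should first be
#' expanded with [augment_expression()].
#'
#' @param E expression matrix aligned with `pattern0`.
#' @param pattern0 initial `nca_pattern`.
#' @param stop_retention stop when an iteration retains more than this
#'   fraction of edges.
#' @param seed integer seed; per-iteration decomposition seeds are
#'   derived from it.
#' @param options solver settings, see [nca_options()].
#' @param max_iterations safety cap on trimming passes.
#' @return An object of class `nca_trim`: `edge_counts` (length
#'   n_iterations + 1, starting at the initial count), `retained_fraction`
#'   per iteration, `final_pattern`, `final_decomposition`,
#'   `n_iterations`, and `converged`.
#' @export
trim_network <- function(E, pattern0, stop_retention = 0.99, seed = 1L,
                         options = nca_options(), max_iterations = 10L) {
  stopifnot(inherits(pattern0, "nca_pattern"))
  M <- ncol(E)
  comp <- check_compliance(pattern0, M)
  if (!comp$criterion3_ok || M < 4L)
    stop("data are under-determined for stepwise trimming (criterion (iii) violated or M < 4); ",
         "generate in-silico replicates with augment_expression() first")

  cur <- pattern0
  edge_counts <- n_edges(cur)
  retained <- numeric(0)
  l <- 0L
  warm <- NULL
  refine_opts <- options
  refine_opts$n_restarts <- 0L  # after iteration 1, refine the warm start only:
                                # re-seeding each pass would let the solver jump
                                # between equivalent optima and destabilise the
                                # per-gene selections
  repeat {
    l <- l + 1L
    dec <- nca_decompose(E, cur, seed = derive_seed(seed, "decompose", l),
                         options = if (is.null(warm)) options else refine_opts,
                         init_P = warm)
    nxt <- trim_iteration(E, cur, dec)
    warm <- dec$P[colnames(nxt$mask), , drop = FALSE]
    r <- n_edges(nxt) / n_edges(cur)
    retained <- c(retained, r)
    edge_counts <- c(edge_counts, n_edges(nxt))
    cur <- nxt
    nca_log("trim", "iteration %d: %d -> %d edges (%.1f%% retained)",
            l, edge_counts[l], edge_counts[l + 1L], 100 * r)
    if (r > stop_retention || l >= max_iterations) break
  }
  final_dec <- nca_decompose(E, cur, seed = derive_seed(seed, "final", 0L),
                             options = refine_opts, init_P = warm)
  structure(list(edge_counts = edge_counts,
                 retained_fraction = retained,
                 final_pattern = cur,
                 final_decomposition = final_dec,
                 n_iterations = l,
                 stop_retention = stop_retention,
                 converged = retained[l] > stop_retention,
                 seed = seed),
            class = "nca_trim")
}

#' @export
print.nca_trim <- function(x, ...) {
  cat(sprintf("Network trimming: %d iteration(s), %d -> %d edges (%s)\n",
              x$n_iterations, x$edge_counts[1],
              x$edge_counts[length(x$edge_counts)],
              if (x$converged) "converged" else "iteration cap reached"))
  for (l in seq_len(x$n_iterations))
    cat(sprintf("  iteration %d: %d edges retained (%.2f%%)\n",
                l, x$edge_counts[l + 1], 100 * x$retained_fraction[l]))
  invisible(x)
}
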