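# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; nothing is read from disk.

# A small pattern from an explicit 0/1 matrix written row-wise.
pat_from <- function(rows, tf_ids = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- tf_ids %||% paste0("TF", seq_len(ncol(m)))
  connectivity_pattern(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Controlled planted instance: genes with 1-2 strong, well-separated
# regulators, so that noise-free stepwise selection is unambiguous.
planted_instance <- function(n_genes = 80, n_tfs = 6, r = 12, fcr = 0.2,
                             seed = 1) {
  net <- generate_network(n_genes = n_genes, n_tfs = n_tfs,
                          max_in_degree = 2, degree_exponent = 1.5,
                          cs_range = c(0.8, 2),
                          regulon_range = c(5, ceiling(n_genes / 2)),
                          seed = seed)
  if (fcr > 0) net <- corrupt_pattern(net, fcr, seed = seed + 100)
  sim <- simulate_expression(net, r = r, noise_level = 0, seed = seed + 200)
  list(net = sim$truth, E = sim$E)
}

# Exhaustive best-subset AICc oracle for small candidate sets, scored
# with the same machine-noise zero floor as the implementation.
best_subset_aicc <- function(e_i, P, candidates) {
  M <- length(e_i)
  floor_ <- sum(e_i^2) * .Machine$double.eps
  best <- Inf
  for (k in seq_len(min(length(candidates), M - 3))) {
    for (cc in utils::combn(candidates, k, simplify = FALSE)) {
      X <- t(P[cc, , drop = FALSE])
      rss <- sum(stats::lm.fit(X, e_i)$residuals^2)
      a <- aicc(if (rss <= floor_) 0 else rss, M, k)
      if (a < best) best <- a
    }
  }
  best
}

# Plain (unregularised, single-start) alternating least-squares solver,
# independent of the package's implementation, for oracle-equivalence
# checks on small noise-free instances.
oracle_als <- function(E, mask, P0, n_iter = 5000, tol = 1e-12) {
  P <- P0
  A <- matrix(0, nrow(E), ncol(mask))
  prev <- Inf
  for (it in seq_len(n_iter)) {
    for (i in seq_len(nrow(E))) {
      idx <- which(mask[i, ] > 0)
      X <- t(P[idx, , drop = FALSE])
      A[i, ] <- 0
      A[i, idx] <- qr.coef(qr(X), E[i, ])
    }
    P <- qr.coef(qr(A), E)
    res <- sqrt(sum((E - A %*% P)^2))
    if (is.finite(prev) && abs(prev - res) <= tol * max(res, 1e-300)) break
    prev <- res
  }
  P / sqrt(rowSums(P^2))
}

# Retained-edge mask of a trim trace, expanded onto the full gene x TF
# grid of the original truth (dropped TFs count as all-removed).
full_mask <- function(trace, truth) {
  out <- matrix(FALSE, nrow(truth$Z_true), ncol(truth$Z_true),
                dimnames = dimnames(truth$Z_true))
  m <- trace$final_pattern$mask
  out[rownames(m), colnames(m)] <- m == 1
  out
}

# One benchmark run at the paper's network scale: generate, corrupt,
# simulate, augment if under-determined, trim.
benchmark_run <- function(seed, r, noise, fcr = 0.20) {
  net <- generate_network(seed = seed)
  net <- corrupt_pattern(net, fcr, seed = seed + 1000)
  sim <- simulate_expression(net, r = r, noise_level = noise,
                             seed = seed + 2000)
  pat0 <- connectivity_pattern(net$Z0)
  plan <- augmentation_plan(sim$E, pat0)
  E <- if (plan$needed)
    augment_expression(sim$E, plan$n_replicates, seed = seed + 3000)
  else sim$E
  trace <- suppressWarnings(trim_network(E, pat0, seed = seed + 4000))
  list(truth = sim$truth, E = E, trace = trace)
}
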