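suppressMessages({

test_that("the default benchmark network matches the designed structure", {
  net <- generate_network(seed = 5)
  Z <- net$Z_true
  expect_identical(dim(Z), c(348L, 20L))
  expect_true(all(rowSums(Z) >= 1))
  expect_true(all(rowSums(Z) <= 6))
  expect_true(all(colSums(Z) >= 5))
  expect_true(all(colSums(Z) <= 90))
  # structural uniqueness criteria hold for the truth itself
  rep <- check_compliance(connectivity_pattern(Z), n_experiments = 348)
  expect_true(rep$criterion1_ok && rep$criterion2_ok)
  # control strengths: signed, bounded away from zero on edges only
  cs <- net$A_true[Z == 1]
  expect_true(all(abs(cs) >= 0.3 & abs(cs) <= 2))
  expect_true(all(net$A_true[Z == 0] == 0))
  expect_gt(sum(cs > 0), 0); expect_gt(sum(cs < 0), 0)
})

test_that("gene in-degrees are consistent with a truncated power law", {
  net <- generate_network(seed = 6)
  degs <- tabulate(net$in_degrees, nbins = 6)
  # maximum-likelihood exponent for P(d) ~ d^-a on 1..6
  nll <- function(a) {
    p <- (1:6)^(-a); p <- p / sum(p)
    -sum(degs * log(p))
  }
  a_hat <- optimize(nll, c(0.1, 6))$minimum
  expect_gt(a_hat, 1); expect_lt(a_hat, 4)
  p_hat <- (1:6)^(-a_hat); p_hat <- p_hat / sum(p_hat)
  gof <- suppressWarnings(chisq.test(degs, p = p_hat))
  expect_gt(gof$p.value, 0.01)
  # decay: single-regulator genes dominate
  expect_identical(which.max(degs), 1L)
  expect_gt(degs[1], sum(degs[-1]))
})

test_that("regulon overlaps span solitary to strongly shared TFs", {
  net <- generate_network(seed = 7)
  Z <- net$Z_true
  shared <- sapply(seq_len(ncol(Z)), function(j) {
    members <- Z[, j] == 1
    mean(rowSums(Z[members, -j, drop = FALSE]) > 0)
  })
  expect_lt(min(shared), 0.35)
  expect_gt(max(shared), 0.6)
})

test_that("a single-TF network degenerates to all degree-1 genes", {
  net <- generate_network(n_genes = 12, n_tfs = 1, max_in_degree = 1,
                          regulon_range = c(5, 12), seed = 8)
  expect_true(all(net$in_degrees == 1))
  expect_equal(unname(colSums(net$Z_true)), 12)
})

test_that("false-edge injection matches the FCR definition exactly", {
  net <- generate_network(seed = 11)
  n_true <- sum(net$Z_true)
  net0 <- corrupt_pattern(net, 0, seed = 12)
  expect_identical(net0$Z0, net0$Z_true)
  net2 <- corrupt_pattern(net, 0.20, seed = 13)
  n_false <- sum(net2$Z0) - n_true
  expect_equal(n_false, round(0.20 * n_true))
  expect_equal(net2$fcr, n_false / n_true)
  # all injected edges have true CS = 0, and Z0 contains the truth
  expect_true(all(net2$A_true[net2$false_edge_mask] == 0))
  expect_true(all(net2$Z0[net2$Z_true == 1] == 1))
  expect_equal(sum(net2$false_edge_mask), n_false)
})

test_that("the important-edge mask takes the top 30% of each regulon", {
  net <- generate_network(seed = 21)
  Z <- net$Z_true
  for (j in seq_len(ncol(Z))) {
    size <- sum(Z[, j])
    expect_equal(sum(net$important_edge_mask[, j]), ceiling(0.3 * size))
    # marked edges dominate unmarked ones in |CS|
    marked <- abs(net$A_true[net$important_edge_mask[, j], j])
    rest <- abs(net$A_true[Z[, j] == 1 & !net$important_edge_mask[, j], j])
    if (length(rest)) expect_gte(min(marked), max(rest))
  }
})

test_that("simulated expression follows E = AP + noise at the stated level", {
  net <- generate_network(seed = 31)
  sim0 <- simulate_expression(net, r = 3, noise_level = 0, seed = 32)
  expect_identical(colnames(sim0$E), paste0("exp", 1:3))
  expect_equal(sim0$E, sim0$truth$A_true %*% sim0$truth$P_true,
               ignore_attr = TRUE)
  sim <- simulate_expression(net, r = 20, noise_level = 0.5, seed = 33)
  resid <- sim$E - sim$truth$A_true %*% sim$truth$P_true
  nominal <- 0.5 * sqrt(mean((sim$truth$A_true %*% sim$truth$P_true)^2))
  expect_lt(abs(sd(resid) - nominal) / nominal, 0.05)
})

test_that("SNR in decibels matches hand arithmetic and its edge cases", {
  expect_equal(snr_db(c(1, 1, 1, 1), c(1.1, 0.9, 1.1, 0.9)),
               10 * log10(4 / 0.04), tolerance = 1e-12)
  expect_identical(snr_db(c(1, 2), c(1, 2)), Inf)
  expect_equal(snr_db(c(1, 2), c(0, 0)), 0)
  expect_error(snr_db(c(0, 0), c(1, 1)), "all-zero true signal")
})

test_that("edge-recovery ROC is perfect for a perfect estimator and null for noise", {
  net <- generate_network(n_genes = 80, n_tfs = 5, max_in_degree = 3,
                          regulon_range = c(5, 40), seed = 41)
  net <- corrupt_pattern(net, 0.25, seed = 42)
  perfect <- structure(list(
    A = net$A_true, P = matrix(0, 5, 3,
      dimnames = list(colnames(net$Z_true), paste0("e", 1:3))),
    residual_norm = 0, scale_record = 1, converged = TRUE,
    n_outer_iterations = 0L, residual_path = numeric(0),
    options = nca_options(), seed = 1L), class = "nca_decomposition")
  true_pat <- connectivity_pattern(net$Z_true)
  roc <- edge_recovery_roc(perfect, true_pat, net, mode = "all")
  expect_equal(roc$auc, 1)
  expect_equal(roc$tpr_at_trim, 1)
  expect_equal(roc$fpr_at_trim, 0)
  # random scores over the full corrupted pattern: AUC near 1/2
  set.seed(43)
  noisy <- perfect
  noisy$A <- matrix(0, nrow(net$Z0), ncol(net$Z0), dimnames = dimnames(net$Z0))
  noisy$A[net$Z0 == 1] <- abs(rnorm(sum(net$Z0)))
  roc2 <- edge_recovery_roc(noisy, connectivity_pattern(net$Z0), net,
                            mode = "all")
  expect_lt(abs(roc2$auc - 0.5), 0.12)
  # important mode counts exactly the masked positives
  roc3 <- edge_recovery_roc(perfect, true_pat, net, mode = "important")
  expect_identical(roc3$n_positives, sum(net$important_edge_mask))
  expect_equal(roc3$tpr_at_trim, 1)
})

test_that("low-noise recovery dominates high-noise recovery (matched seeds)", {
  aucs <- sapply(c(0.1, 0.5), function(noise) {
    mean(sapply(71:72, function(s) {
      net <- generate_network(n_genes = 100, n_tfs = 6, max_in_degree = 3,
                              regulon_range = c(5, 50), seed = s)
      net <- corrupt_pattern(net, 0.2, seed = s + 10)
      sim <- simulate_expression(net, r = 8, noise_level = noise, seed = s + 20)
      pat0 <- connectivity_pattern(net$Z0)
      tr <- suppressWarnings(trim_network(sim$E, pat0, seed = s + 30))
      edge_recovery_roc(tr$final_decomposition, tr$final_pattern, net,
                        mode = "important")$auc
    }))
  })
  expect_gte(aucs[1], aucs[2])
})

test_that("trimmed TFAs reach 10 dB for most TFs at low noise", {
  res <- benchmark_run(seed = 81, r = 9, noise = 0.1)
  decF <- res$trace$final_decomposition
  P_true <- res$truth$P_true
  # compare on the original (pre-augmentation) experiment columns
  keep_tfs <- rownames(decF$P)
  P_hat <- decF$P[, colnames(P_true), drop = FALSE]
  snrs <- sapply(keep_tfs, function(tf) {
    d <- align_tfa(P_hat[tf, , drop = FALSE], P_true[tf, , drop = FALSE])
    snr_db(P_true[tf, ], drop(d))
  })
  expect_gte(mean(snrs > 10), 0.9)
})

})
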