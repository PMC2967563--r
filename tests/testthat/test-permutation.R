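suppressMessages({

test_that("closed-pool sampling without replacement is a row permutation", {
  E <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  out <- scramble_rows(E, 5, seed = 3, replace = FALSE)
  expect_identical(dim(out), dim(E))
  expect_equal(out[order(out[, 1]), ], unname(E[order(E[, 1]), ]),
               ignore_attr = TRUE)
  # determinism
  expect_identical(scramble_rows(E, 3, seed = 8),
                   scramble_rows(E, 3, seed = 8))
  expect_error(scramble_rows(E, 9, seed = 1, replace = FALSE), "smaller")
})

test_that("scrambled rows follow the pool's column-wise distribution", {
  set.seed(11)
  pool <- matrix(rnorm(5000 * 3), 5000, 3,
                 dimnames = list(paste0("g", 1:5000), NULL))
  out <- scramble_rows(pool, 1000, seed = 12)
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(out[, j], pool[, j]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("sign alignment flips anti-correlated TFAs and never the product", {
  mk <- function(A, P) structure(list(
    A = A, P = P, residual_norm = 0,
    scale_record = setNames(rep(1, nrow(P)), rownames(P)),
    converged = TRUE, n_outer_iterations = 0L, residual_path = numeric(0),
    options = nca_options(), seed = 1L), class = "nca_decomposition")
  set.seed(21)
  P_real <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("TF", 1:3), NULL))
  A_real <- matrix(rnorm(15), 5, 3,
                   dimnames = list(paste0("g", 1:5), paste0("TF", 1:3)))
  real <- mk(A_real, P_real)
  # null: TF1 flipped, TF2 equal, TF3 random
  P_null <- P_real
  P_null[1, ] <- -P_real[1, ]
  P_null[3, ] <- rnorm(4)
  null <- mk(A_real, P_null)
  prod0 <- null$A %*% null$P
  out <- align_signs(null, real)
  expect_equal(out$P[1, ], real$P[1, ])          # flipped back
  expect_equal(out$P[2, ], null$P[2, ])          # unchanged
  for (j in 1:3)
    expect_gte(cor(out$P[j, ], real$P[j, ]), 0)  # post-condition
  expect_lt(max(abs(out$A %*% out$P - prod0)), 1e-12)
  # zero-variance row: no flip, warning
  null2 <- mk(A_real, P_null)
  null2$P[2, ] <- 0
  expect_warning(align_signs(null2, real), "zero-variance")
})

test_that("a small null ensemble runs end to end with finite summaries", {
  net <- generate_network(n_genes = 30, n_tfs = 4, max_in_degree = 2,
                          regulon_range = c(5, 20), seed = 31)
  sim <- simulate_expression(net, r = 5, noise_level = 0.3, seed = 32)
  pat <- connectivity_pattern(net$Z_true)
  dec <- nca_decompose(sim$E, pat, seed = 33)
  expect_warning(
    nulls <- build_nulls(sim$E, pat, dec, n = 5, seed = 34),
    "below the recommended minimum")
  expect_identical(dim(nulls$tfa_samples), c(4L, 5L, 5L))
  expect_true(all(is.finite(nulls$medians)))
  expect_true(all(is.finite(nulls$mads)) && all(nulls$mads >= 0))
  expect_identical(nulls$n_failed, 0L)
  # reproducibility: the whole ensemble is bit-stable
  nulls2 <- suppressWarnings(build_nulls(sim$E, pat, dec, n = 5, seed = 34))
  expect_identical(nulls$tfa_samples, nulls2$tfa_samples)
})

test_that("z-scores and p-values follow the median/MAD rule", {
  L <- 3; M <- 4
  tfs <- paste0("TF", 1:L)
  P_real <- matrix(0, L, M, dimnames = list(tfs, paste0("e", 1:M)))
  meds <- matrix(0, L, M, dimnames = dimnames(P_real))
  mads <- matrix(1, L, M, dimnames = dimnames(P_real))
  nulls <- structure(list(tfa_samples = array(0, c(L, M, 1)),
                          medians = meds, mads = mads, n = 200L,
                          n_failed = 0L), class = "nca_nulls")
  mk <- function(P) structure(list(
    A = matrix(0, 1, L, dimnames = list("g1", tfs)), P = P,
    residual_norm = 0, scale_record = setNames(rep(1, L), tfs),
    converged = TRUE, n_outer_iterations = 0L, residual_path = numeric(0),
    options = nca_options(), seed = 1L), class = "nca_decomposition")
  # TFA equal to the null median: z = 0, p = 1
  calls <- call_perturbed(mk(P_real), nulls, alpha = 0.1)
  expect_true(all(calls$z == 0))
  expect_true(all(calls$p == 1))
  expect_false(any(calls$summary$significant))
  # TFA at median + 1.96 * 1.4826 * MAD: p ~ 0.05
  P2 <- P_real; P2[1, 1] <- 1.96 * 1.4826
  calls2 <- call_perturbed(mk(P2), nulls, alpha = 0.1)
  expect_equal(calls2$p[1, 1], 0.04999579, tolerance = 1e-4)
  expect_true(calls2$summary$significant[1])
  # MAD = 0 with a deviation: infinite z, p = 0, degeneracy flagged
  nulls0 <- nulls; nulls0$mads[2, ] <- 0
  P3 <- P_real; P3[2, 2] <- 0.5
  calls3 <- call_perturbed(mk(P3), nulls0, alpha = 0.1)
  expect_identical(calls3$p[2, 2], 0)
  expect_true(calls3$summary$degenerate[2])
  # adjusted p-values never fall below raw
  expect_true(all(calls2$summary$p_adjusted >= calls2$summary$p_value - 1e-15))
})

test_that("null-pool data produce few false perturbation calls", {
  # real data drawn from the very pool used for scrambling: calls at
  # alpha should stay within the binomial tolerance alpha + 3*se
  net <- generate_network(n_genes = 40, n_tfs = 8, max_in_degree = 2,
                          degree_exponent = 1.5, regulon_range = c(5, 20),
                          seed = 41)
  pat <- connectivity_pattern(net$Z_true)
  set.seed(42)
  pool <- matrix(rnorm(400 * 4), 400, 4,
                 dimnames = list(paste0("p", 1:400), paste0("e", 1:4)))
  E <- pool[sample.int(400, 40), ]
  rownames(E) <- rownames(pat$mask)
  dec <- nca_decompose(E, pat, seed = 43)
  nulls <- suppressWarnings(build_nulls(pool, pat, dec, n = 80, seed = 44))
  calls <- call_perturbed(dec, nulls, alpha = 0.1, mode = "adjusted")
  frac <- mean(calls$summary$significant)
  expect_lte(frac, 0.1 + 3 * sqrt(0.1 * 0.9 / 8))
})

test_that("perturbation calls are invariant to the decomposition's sign freedom", {
  net <- generate_network(n_genes = 30, n_tfs = 4, max_in_degree = 2,
                          regulon_range = c(5, 20), seed = 51)
  sim <- simulate_expression(net, r = 5, noise_level = 0.3, seed = 52)
  pat <- connectivity_pattern(net$Z_true)
  dec <- nca_decompose(sim$E, pat, seed = 53)
  flipped <- dec
  flipped$P[c(1, 3), ] <- -flipped$P[c(1, 3), ]
  flipped$A[, c(1, 3)] <- -flipped$A[, c(1, 3)]
  n1 <- suppressWarnings(build_nulls(sim$E, pat, dec, n = 30, seed = 54))
  n2 <- suppressWarnings(build_nulls(sim$E, pat, flipped, n = 30, seed = 54))
  c1 <- call_perturbed(dec, n1, alpha = 0.1)
  c2 <- call_perturbed(flipped, n2, alpha = 0.1)
  expect_equal(c1$p, c2$p, tolerance = 1e-10)
  expect_identical(c1$summary$significant, c2$summary$significant)
})

test_that("planted perturbed TFs land in the tails of pure-noise nulls", {
  net <- generate_network(n_genes = 50, n_tfs = 6, max_in_degree = 2,
                          regulon_range = c(5, 25), seed = 61)
  sim <- simulate_expression(net, r = 5, noise_level = 0.2, seed = 62,
                             perturb_fraction = 0.33, perturb_effect = 4)
  pat <- connectivity_pattern(net$Z_true)
  dec <- nca_decompose(sim$E, pat, seed = 63)
  set.seed(64)
  pool <- matrix(rnorm(500 * 5, sd = sd(sim$E)), 500, 5,
                 dimnames = list(paste0("p", 1:500), colnames(sim$E)))
  nulls <- suppressWarnings(build_nulls(pool, pat, dec, n = 60, seed = 65))
  calls <- call_perturbed(dec, nulls, alpha = 0.1)
  hit <- calls$summary$significant[match(sim$truth$perturbed_tfs,
                                         calls$summary$tf_id)]
  expect_true(mean(hit) >= 0.5)
})

})
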