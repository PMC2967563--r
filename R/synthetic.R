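#' Generate a ground-truth synthetic regulatory network
#'
#' Builds a benchmark network that mimics key structural features of
#' mammalian transcriptional networks: the number of TFs regulating a
#' gene follows a truncated power-law decay, regulon sizes span a wide
#' range (a handful of genes up to most of the network), and TFs differ
#' in how much of their regulon is shared with other TFs (roughly 20% to
#' 80%). True control strengths are signed with magnitudes drawn
#' uniformly from `cs_range`, bounded away from zero so that every
#' planted edge is detectable in principle, and edges whose |CS| ranks in
#' the top 30% of their TF's regulon are marked "important".
#'
#' The realised network is re-drawn (up to `max_retries` times) until it
#' satisfies the uniqueness criteria (i) and (ii) and the configured
#' regulon-size range, so the truth itself is structurally well posed.
#'
#' @param n_genes,n_tfs network dimensions (defaults 348 x 20).
#' @param degree_exponent exponent of the truncated power law of
#'   TFs-per-gene (default 2).
#' @param max_in_degree maximum number of TFs regulating one gene
#'   (default 6).
#' @param regulon_range admissible regulon sizes (default c(5, 90)).
#' @param overlap_range range of per-TF overlap propensities steering how
#'   much of each regulon is shared (default c(0.2, 0.8)).
#' @param cs_range magnitude range of true control strengths.
#' @param important_top fraction of each regulon (by |CS|) marked
#'   important (default 0.3).
#' @param seed integer seed.
#' @param max_retries attempts to realise a structurally valid network.
#' @return An object of class `nca_truth`: `Z_true` (binary N x L
#'   matrix), `A_true`, `important_edge_mask`, `in_degrees`, `seed`; the
#'   corrupted pattern, expression data and TFA truth are added by
#'   [corrupt_pattern()] and [simulate_expression()].
#' @export
generate_network <- function(n_genes = 348L, n_tfs = 20L,
                             degree_exponent = 2, max_in_degree = 6L,
                             regulon_range = c(5L, 90L),
                             overlap_range = c(0.2, 0.8),
                             cs_range = c(0.3, 2), important_top = 0.3,
                             seed = 1L, max_retries = 20L) {
  stopifnot(n_genes >= n_tfs, max_in_degree >= 1L, max_in_degree <= n_tfs)
  gene_ids <- paste0("gene", seq_len(n_genes))
  tf_ids <- paste0("TF", seq_len(n_tfs))

  Z <- with_rng_seed(seed, {
    degree_pmf <- seq_len(max_in_degree)^(-degree_exponent)
    found <- NULL
    for (attempt in seq_len(max_retries)) {
      cand <- realize_topology(n_genes, n_tfs, degree_pmf, regulon_range,
                               overlap_range, max_in_degree)
      if (is.null(cand)) next
      dimnames(cand) <- list(gene_ids, tf_ids)
      rep <- check_compliance(connectivity_pattern(cand),
                              n_experiments = n_genes)
      sizes <- colSums(cand)
      if (rep$criterion1_ok && rep$criterion2_ok &&
          all(sizes >= regulon_range[1]) && all(sizes <= regulon_range[2])) {
        found <- cand
        break
      }
    }
    if (is.null(found))
      stop("could not realise a structurally valid network in ", max_retries,
           " attempts; relax the degree or regulon constraints")
    found
  })

  A_true <- with_rng_seed(derive_seed(seed, "cs"), {
    A <- matrix(0, n_genes, n_tfs, dimnames = dimnames(Z))
    ne <- sum(Z)
    A[Z == 1] <- sample(c(-1, 1), ne, replace = TRUE) *
      stats::runif(ne, cs_range[1], cs_range[2])
    A
  })

  nca_log("synthetic",
          "network realised: %d edges, in-degrees 1..%d (mean %.2f), regulons %d..%d",
          sum(Z), max(rowSums(Z)), mean(rowSums(Z)), min(colSums(Z)), max(colSums(Z)))

  structure(list(Z_true = Z, A_true = A_true, P_true = NULL,
                 Z0 = NULL, false_edge_mask = NULL,
                 important_edge_mask = important_edges(A_true, Z, important_top),
                 in_degrees = rowSums(Z), fcr = NULL, noise_level = NULL,
                 important_top = important_top, seed = seed),
            class = "nca_truth")
}

# Configuration-model style bipartite assignment: gene in-degrees from the
# truncated power law, TF capacities log-uniform over the regulon range,
# multi-regulator genes steered toward high-overlap TFs. Returns NULL when
# a feasibility fix-up fails (caller retries).
realize_topology <- function(n_genes, n_tfs, degree_pmf, regulon_range,
                             overlap_range, max_in_degree) {
  degs <- sample.int(length(degree_pmf), n_genes, replace = TRUE,
                     prob = degree_pmf)
  target <- exp(stats::runif(n_tfs, log(regulon_range[1]),
                             log(min(regulon_range[2], n_genes / 2))))
  target <- target * sum(degs) / sum(target)
  overlap <- stats::runif(n_tfs, overlap_range[1], overlap_range[2])
  Z <- matrix(0, n_genes, n_tfs)
  remaining <- target
  for (i in sample.int(n_genes)) {
    d <- degs[i]
    w <- pmax(remaining, 0.05) * if (d == 1L) (1 - overlap) else overlap
    pick <- sample.int(n_tfs, d, prob = w)
    Z[i, pick] <- 1
    remaining[pick] <- remaining[pick] - 1
  }
  # top up regulons below the minimum size with genes that still have slack
  sizes <- colSums(Z)
  for (j in which(sizes < regulon_range[1])) {
    need <- regulon_range[1] - sizes[j]
    cand <- which(Z[, j] == 0 & rowSums(Z) < max_in_degree)
    if (length(cand) < need) return(NULL)
    add <- cand[sample.int(length(cand), need)]
    Z[add, j] <- 1
  }
  # shave regulons above the maximum, never orphaning a gene
  sizes <- colSums(Z)
  for (j in which(sizes > regulon_range[2])) {
    excess <- sizes[j] - regulon_range[2]
    cand <- which(Z[, j] == 1 & rowSums(Z) > 1)
    if (length(cand) < excess) return(NULL)
    drop <- cand[sample.int(length(cand), excess)]
    Z[drop, j] <- 0
  }
  if (any(rowSums(Z) == 0)) return(NULL)
  Z
}

#' Important-edge mask of a true control-strength matrix
#'
#' For each TF, marks the `ceiling(top * regulon size)` edges with the
#' largest |CS| as important; ties are broken deterministically by gene
#' order.
#'
#' @param A control-strength matrix.
#' @param Z binary pattern of true edges (defaults to the nonzeros of A).
#' @param top fraction of each regulon marked important.
#' @return A logical matrix of the same shape as `A`.
#' @export
important_edges <- function(A, Z = (A != 0) * 1, top = 0.3) {
  mask <- matrix(FALSE, nrow(A), ncol(A), dimnames = dimnames(A))
  for (j in seq_len(ncol(A))) {
    members <- which(Z[, j] == 1)
    if (!length(members)) next
    n_top <- ceiling(top * length(members))
    ranked <- members[order(-abs(A[members, j]), members)]
    mask[ranked[seq_len(n_top)], j] <- TRUE
  }
  mask
}

#' Inject false edges into the true pattern
#'
#' Adds `round(fcr * n_true_edges)` false edges uniformly over the zero
#' cells of the true pattern, where the false connection rate (FCR) is
#' defined as the number of edges present in the initial pattern but
#' absent in truth divided by the number of true edges. The corrupted
#' pattern is a superset of the truth by construction and every injected
#' edge has true CS = 0.
#'
#' @param truth an `nca_truth` from [generate_network()].
#' @param fcr requested false connection rate.
#' @param seed integer seed.
#' @return The truth object with `Z0`, `false_edge_mask` and the achieved
#'   `fcr` filled in.
#' @export
corrupt_pattern <- function(truth, fcr, seed = 1L) {
  stopifnot(inherits(truth, "nca_truth"), fcr >= 0)
  Z <- truth$Z_true
  n_true <- sum(Z)
  n_false <- round(fcr * n_true)
  zero_cells <- which(Z == 0)
  if (length(zero_cells) < n_false)
    stop("not enough zero cells to place ", n_false, " false edges")
  false_idx <- with_rng_seed(seed,
    zero_cells[sample.int(length(zero_cells), n_false)])
  Z0 <- Z
  Z0[false_idx] <- 1
  fmask <- matrix(FALSE, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  fmask[false_idx] <- TRUE
  truth$Z0 <- Z0
  truth$false_edge_mask <- fmask
  truth$fcr <- n_false / n_true
  truth
}

#' Simulate expression data from a synthetic truth
#'
#' Draws true TFA profiles (i.i.d. Gaussian per TF and condition) and
#' produces E = A_true P_true + noise, with homoscedastic Gaussian noise
#' whose standard deviation is `noise_level` times the RMS of the
#' noise-free signal, so the level is a relative magnitude. Optionally a
#' fraction of TFs is planted as "perturbed" by shifting their TFA rows
#' by a constant effect, for benchmarking the permutation test.
#'
#' The TFA scale `tfa_sd` sets the absolute magnitude of the simulated
#' log-ratios (with the default control strengths the pooled SD of E is
#' about 0.6-0.9, typical of two-channel microarray log-ratios). The
#' absolute scale matters for exactly one stage: the in-silico
#' augmentation sampler draws replicate noise proportional to both the
#' cell magnitude and the pooled data SD, so data simulated much larger
#' than real log-ratios would receive unrealistically destructive
#' replicate noise.
#'
#' @param truth an `nca_truth` (corrupted or not).
#' @param r number of experiments (columns) to simulate.
#' @param noise_level relative noise level (e.g. 0.1 or 0.5).
#' @param seed integer seed.
#' @param tfa_sd standard deviation of the true TFA draws (default 0.5).
#' @param perturb_fraction fraction of TFs planted as perturbed
#'   (default 0).
#' @param perturb_effect TFA shift applied to perturbed TFs, in units of
#'   `tfa_sd`.
#' @return A list of class `nca_simulation`: `E` (expression matrix,
#'   columns exp1..expr) and `truth`, the input truth updated with
#'   `P_true` (L x r), `noise_level` and `perturbed_tfs`.
#' @export
simulate_expression <- function(truth, r, noise_level, seed = 1L,
                                tfa_sd = 0.5, perturb_fraction = 0,
                                perturb_effect = 3) {
  stopifnot(inherits(truth, "nca_truth"), r >= 1, noise_level >= 0)
  L <- ncol(truth$Z_true)
  sim <- with_rng_seed(seed, {
    P <- matrix(stats::rnorm(L * r, sd = tfa_sd), L, r)
    perturbed <- character(0)
    if (perturb_fraction > 0) {
      k <- max(1L, round(perturb_fraction * L))
      idx <- sample.int(L, k)
      P[idx, ] <- P[idx, ] + perturb_effect * tfa_sd
      perturbed <- colnames(truth$Z_true)[idx]
    }
    E0 <- truth$A_true %*% P
    s <- sqrt(mean(E0^2))
    E <- E0 + matrix(stats::rnorm(length(E0)), nrow(E0), ncol(E0)) *
      (noise_level * s)
    list(P = P, E = E, perturbed = perturbed)
  })
  dimnames(sim$P) <- list(colnames(truth$Z_true), paste0("exp", seq_len(r)))
  dimnames(sim$E) <- list(rownames(truth$Z_true), paste0("exp", seq_len(r)))
  truth$P_true <- sim$P
  truth$noise_level <- noise_level
  truth$perturbed_tfs <- sim$perturbed
  structure(list(E = sim$E, truth = truth), class = "nca_simulation")
}

#' Signal-to-noise ratio of reconstructed TFAs, in decibels
#'
#' `10 * log10(sum(true^2) / sum((true - derived)^2))`. The derived
#' signals must already be aligned to the truth in scale and sign (see
#' [align_tfa()]). A zero error sum returns `Inf`; a derived signal of
#' all zeros gives 0 dB by construction.
#'
#' @param tfa_true,tfa_derived equally-shaped numeric arrays.
#' @return SNR in dB (scalar).
#' @export
snr_db <- function(tfa_true, tfa_derived) {
  if (!all(dim(as.matrix(tfa_true)) == dim(as.matrix(tfa_derived))))
    stop("shapes of true and derived TFAs differ")
  ss_true <- sum(tfa_true^2)
  if (ss_true == 0) stop("SNR undefined for an all-zero true signal")
  ss_err <- sum((tfa_true - tfa_derived)^2)
  if (ss_err == 0) return(Inf)
  10 * log10(ss_true / ss_err)
}

#' Align derived TFA rows to the truth in scale and sign
#'
#' The decomposition determines each TFA row only up to a scalar; before
#' computing errors against the truth, each derived row is rescaled by
#' the least-squares factor `<true, derived> / <derived, derived>`, which
#' also fixes the sign.
#'
#' @param derived,true TFA matrices with matching rows.
#' @return The rescaled derived matrix.
#' @export
align_tfa <- function(derived, true) {
  stopifnot(all(dim(derived) == dim(true)))
  for (j in seq_len(nrow(derived))) {
    denom <- sum(derived[j, ]^2)
    if (denom == 0) next
    derived[j, ] <- derived[j, ] * sum(true[j, ] * derived[j, ]) / denom
  }
  derived
}

#' ROC analysis of edge recovery against the synthetic truth
#'
#' Ranks the candidate edges of the initial corrupted pattern by the
#' estimated |CS| of a decomposition (edges trimmed away score 0) and
#' sweeps a threshold to produce a ROC curve. Positives are the true
#' edges (`mode = "all"`) or only the true important edges
#' (`mode = "important"`); all other initial-pattern edges count as
#' negatives. The discrete trimmed network itself gives one operating
#' point, whose TPR/FPR are reported separately.
#'
#' @param dec final `nca_decomposition` (on the trimmed pattern).
#' @param pattern final trimmed `nca_pattern`.
#' @param truth corrupted `nca_truth` (needs `Z0`).
#' @param mode `"all"` or `"important"`.
#' @return A list of class `nca_roc`: `curve` (data.frame fpr/tpr),
#'   `auc`, `tpr_at_trim`, `fpr_at_trim`, `mode`, `n_positives`,
#'   `n_negatives`.
#' @export
edge_recovery_roc <- function(dec, pattern, truth,
                              mode = c("all", "important")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "nca_truth"))
  if (is.null(truth$Z0)) stop("truth has no corrupted pattern; run corrupt_pattern() first")
  Z0 <- truth$Z0
  scores <- matrix(0, nrow(Z0), ncol(Z0), dimnames = dimnames(Z0))
  common_tfs <- intersect(colnames(dec$A), colnames(Z0))
  scores[rownames(dec$A), common_tfs] <- abs(dec$A[, common_tfs])
  retained <- matrix(FALSE, nrow(Z0), ncol(Z0), dimnames = dimnames(Z0))
  retained[rownames(pattern$mask), colnames(pattern$mask)] <-
    pattern$mask == 1

  universe <- which(Z0 == 1)
  pos_mask <- if (mode == "all") truth$Z_true == 1 else truth$important_edge_mask
  labels <- pos_mask[universe]
  if (!any(labels)) stop("no positive edges under mode '", mode, "'")
  sc <- scores[universe]

  roc <- pROC::roc(response = labels, predictor = sc,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = rev(1 - roc$specificities),
                      tpr = rev(roc$sensitivities))
  kept <- retained[universe]
  structure(list(curve = curve, auc = as.numeric(roc$auc),
                 tpr_at_trim = sum(kept & labels) / sum(labels),
                 fpr_at_trim = sum(kept & !labels) / sum(!labels),
                 mode = mode,
                 n_positives = sum(labels), n_negatives = sum(!labels)),
            class = "nca_roc")
}

#' @export
print.nca_roc <- function(x, ...) {
  cat(sprintf("Edge-recovery ROC (%s edges): AUC %.3f; trimmed operating point TPR %.3f / FPR %.3f (%d pos, %d neg)\n",
              x$mode, x$auc, x$tpr_at_trim, x$fpr_at_trim,
              x$n_positives, x$n_negatives))
  invisible(x)
}
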