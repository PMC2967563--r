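#' Scramble expression rows from a genome-wide pool
#'
#' Draws `n_rows` expression rows from a genome-wide pool (usually a
#' superset of the analysed network's genes) to build one randomised
#' dataset: gene identities are destroyed while the column-wise
#' expression distribution is preserved and the connectivity is kept
#' unchanged by the caller. By default rows are sampled with replacement,
#' the natural choice when the pool is much larger than the network;
#' sampling without replacement from a pool equal to the network's own
#' data yields an exact row permutation.
#'
#' @param E_genome pool expression matrix (same experiment columns as the
#'   analysed data).
#' @param n_rows number of rows to draw.
#' @param seed integer seed.
#' @param replace sample with replacement (default `TRUE`).
#' @return A matrix of `n_rows` pool rows, in draw order; the caller
#'   assigns them to the network's genes.
#' @export
scramble_rows <- function(E_genome, n_rows, seed, replace = TRUE) {
  if (!replace && nrow(E_genome) < n_rows)
    stop("pool is smaller than the network and replace = FALSE")
  if (nrow(E_genome) < 1L) stop("empty pool")
  idx <- with_rng_seed(seed, sample.int(nrow(E_genome), n_rows, replace = replace))
  out <- E_genome[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align the signs of a null decomposition to the real one
#'
#' The decomposition leaves each TF's sign free (only the product AP is
#' determined up to per-TF scaling). Before comparing null TFAs to the
#' real ones, each TF whose null TFA profile correlates negatively with
#' the real profile has its P row and A column flipped by -1, leaving AP
#' unchanged. A zero-variance TFA row has an undefined correlation and is
#' left unflipped with a warning.
#'
#' @param null_dec decomposition of a scrambled dataset.
#' @param real_dec decomposition of the real data (same TF set).
#' @return `null_dec` with aligned signs.
#' @export
align_signs <- function(null_dec, real_dec) {
  stopifnot(inherits(null_dec, "nca_decomposition"),
            inherits(real_dec, "nca_decomposition"))
  if (!identical(rownames(null_dec$P), rownames(real_dec$P)))
    stop("TF sets of the two decompositions differ")
  for (j in seq_len(nrow(null_dec$P))) {
    r <- suppressWarnings(stats::cor(null_dec$P[j, ], real_dec$P[j, ]))
    if (is.na(r)) {
      nca_warn("align", "zero-variance TFA row for %s; sign left as is",
               rownames(null_dec$P)[j])
      next
    }
    if (r < 0) {
      null_dec$P[j, ] <- -null_dec$P[j, ]
      null_dec$A[, j] <- -null_dec$A[, j]
    }
  }
  null_dec
}

#' Build TFA null distributions from genome-scrambled data
#'
#' Repeats scramble -> decompose -> sign-align `n` times against the
#' trimmed connectivity, collecting for every TF and experiment the null
#' TFA values and their median and raw median absolute deviation (MAD,
#' unscaled; the normal-consistency constant is applied by
#' [call_perturbed()]). A null decomposition that fails is retried with a
#' fresh derived seed up to `retry_cap` times; exhausted retries are
#' counted and reported.
#'
#' @param E_genome pool expression matrix; must have the same experiment
#'   columns as the data `real_dec` was fitted to (if the real data were
#'   augmented, augment the pool the same way).
#' @param pattern trimmed `nca_pattern` (the final connectivity).
#' @param real_dec decomposition of the real data on `pattern`.
#' @param n number of scrambled datasets (at least 200 recommended; a
#'   warning is emitted below that).
#' @param seed integer seed for the whole ensemble.
#' @param options solver settings for the null decompositions.
#' @param replace passed to [scramble_rows()].
#' @param retry_cap retries per failed null decomposition.
#' @return An object of class `nca_nulls`: `tfa_samples` (L x M x n
#'   array), `medians` and `mads` (L x M), `n`, `n_failed`.
#' @export
build_nulls <- function(E_genome, pattern, real_dec, n = 270L, seed = 1L,
                        options = nca_options(), replace = TRUE,
                        retry_cap = 5L) {
  stopifnot(inherits(pattern, "nca_pattern"))
  if (n < 200L)
    nca_warn("nulls", "n = %d null networks is below the recommended minimum of 200", n)
  if (ncol(E_genome) != ncol(real_dec$P))
    stop("pool and real data must have the same experiment columns")
  Z <- pattern$mask
  L <- ncol(Z); M <- ncol(real_dec$P)
  samples <- array(NA_real_, c(L, M, n),
                   dimnames = list(colnames(Z), colnames(real_dec$P), NULL))
  n_failed <- 0L
  for (b in seq_len(n)) {
    dec <- NULL
    for (try_i in 0:retry_cap) {
      s <- derive_seed(seed, "scramble", b * (retry_cap + 1L) + try_i)
      E_rand <- scramble_rows(E_genome, nrow(Z), seed = s, replace = replace)
      rownames(E_rand) <- rownames(Z)
      dec <- tryCatch(
        suppressWarnings(nca_decompose(E_rand, pattern,
                                       seed = derive_seed(s, "null-init"),
                                       options = options)),
        error = function(e) NULL)
      if (!is.null(dec)) break
    }
    if (is.null(dec)) {
      n_failed <- n_failed + 1L
      next
    }
    dec <- suppressWarnings(align_signs(dec, real_dec))
    samples[, , b] <- dec$P
  }
  if (n_failed > 0L)
    nca_warn("nulls", "%d of %d null decompositions failed after retries", n_failed, n)
  medians <- apply(samples, c(1, 2), stats::median, na.rm = TRUE)
  mads <- apply(samples, c(1, 2), stats::mad, constant = 1, na.rm = TRUE)
  structure(list(tfa_samples = samples, medians = medians, mads = mads,
                 n = as.integer(n), n_failed = n_failed),
            class = "nca_nulls")
}

#' Call significantly perturbed TFs against the null ensemble
#'
#' Computes per-TF, per-experiment robust z-scores of the real TFAs
#' against the scrambled-genome null distributions,
#' `z = (TFA_real - null median) / (null MAD * 1.4826)`, where the
#' constant 1.4826 makes the MAD a consistent estimate of the standard
#' deviation under a Gaussian null so that two-tailed normal p-values
#' are calibrated. Each TF's summary p-value is the minimum across
#' experiments, then Benjamini-Hochberg adjusted across TFs. A TF is
#' flagged significant when its raw (default) or adjusted summary
#' p-value falls below `alpha`.
#'
#' A null MAD of zero makes |z| infinite; such entries are reported with
#' p = 0 and a degeneracy flag.
#'
#' @param real_dec decomposition of the real data.
#' @param nulls an `nca_nulls` ensemble covering the same TFs.
#' @param alpha significance level (default 0.1).
#' @param mode `"raw"` or `"adjusted"`: which summary p-value the
#'   significance flag uses.
#' @return An object of class `nca_tfcalls`: `summary` data.frame with
#'   per-TF `p_value`, `p_adjusted`, `significant`, `degenerate`; and
#'   matrices `z` and `p` per TF/experiment.
#' @export
call_perturbed <- function(real_dec, nulls, alpha = 0.1,
                           mode = c("raw", "adjusted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nulls, "nca_nulls"))
  if (!identical(rownames(real_dec$P), rownames(nulls$medians)))
    stop("null ensemble does not cover the decomposition's TFs")
  scale <- nulls$mads * 1.4826
  dev <- real_dec$P - nulls$medians
  z <- dev / scale
  degenerate_cell <- scale == 0
  z[degenerate_cell & dev == 0] <- 0
  z[degenerate_cell & dev > 0] <- Inf
  z[degenerate_cell & dev < 0] <- -Inf
  p <- 2 * stats::pnorm(-abs(z))
  p[is.infinite(z)] <- 0
  p_tf <- apply(p, 1, min)
  p_adj <- stats::p.adjust(p_tf, method = "BH")
  sig <- (if (mode == "raw") p_tf else p_adj) < alpha
  degenerate <- rowSums(degenerate_cell & dev != 0) > 0
  structure(list(
    summary = data.frame(tf_id = rownames(real_dec$P),
                         p_value = p_tf, p_adjusted = p_adj,
                         significant = sig, degenerate = degenerate,
                         row.names = NULL, stringsAsFactors = FALSE),
    z = z, p = p, alpha = alpha, mode = mode),
    class = "nca_tfcalls")
}

#' @export
print.nca_tfcalls <- function(x, ...) {
  n_sig <- sum(x$summary$significant)
  cat(sprintf("TF perturbation calls (%s p < %g): %d of %d TFs significant\n",
              x$mode, x$alpha, n_sig, nrow(x$summary)))
  if (n_sig > 0)
    cat("  ", paste(x$summary$tf_id[x$summary$significant], collapse = ", "), "\n")
  invisible(x)
}
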