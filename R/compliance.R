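#' Check the three structural criteria for a unique decomposition
#'
#' A connectivity pattern admits an essentially unique constrained
#' decomposition (up to per-TF scaling) when three criteria hold:
#' (i) every TF regulates at most N - L + 1 genes, where N is the number
#' of genes and L the number of TFs; (ii) no TF's regulon is a subset of
#' another TF's regulon; (iii) no gene is regulated by more TFs than
#' there are experiments. Criterion (iii) is the one most often violated
#' for mammalian networks with few arrays; it can be restored by
#' in-silico data augmentation (see [augment_expression()]).
#'
#' All three criteria are always evaluated and every violating TF or gene
#' is listed, not just the first.
#'
#' @param pattern an `nca_pattern`.
#' @param n_experiments number of expression measurements M.
#' @return An object of class `nca_compliance`: flags `criterion1_ok`,
#'   `criterion2_ok`, `criterion3_ok`, label vectors `offending_tfs`
#'   (criteria i/ii) and `offending_genes` (criterion iii), and
#'   `max_regulators_per_gene`.
#' @export
check_compliance <- function(pattern, n_experiments) {
  stopifnot(inherits(pattern, "nca_pattern"))
  Z <- pattern$mask
  N <- nrow(Z); L <- ncol(Z)
  regulon_sizes <- colSums(Z)
  in_degree <- rowSums(Z)

  bad1 <- colnames(Z)[regulon_sizes > N - L + 1]

  # regulon j is a subset of regulon k iff |regulon_j intersect regulon_k| = |regulon_j|
  overlap <- crossprod(Z)                   # L x L shared-gene counts
  subset_of <- sweep(overlap, 1, regulon_sizes, "==")
  diag(subset_of) <- FALSE
  bad2 <- colnames(Z)[rowSums(subset_of) > 0]

  bad3 <- rownames(Z)[in_degree > n_experiments]

  structure(list(
    criterion1_ok = length(bad1) == 0L,
    criterion2_ok = length(bad2) == 0L,
    criterion3_ok = length(bad3) == 0L,
    offending_tfs = union(bad1, bad2),
    offending_genes = bad3,
    max_regulators_per_gene = as.integer(max(in_degree)),
    n_experiments = as.integer(n_experiments)
  ), class = "nca_compliance")
}

#' @export
print.nca_compliance <- function(x, ...) {
  ok <- function(b) if (b) "ok" else "VIOLATED"
  cat("Compliance of the connectivity pattern:\n")
  cat(sprintf("  (i)   regulon sizes <= N - L + 1 : %s\n", ok(x$criterion1_ok)))
  cat(sprintf("  (ii)  no regulon nested in another: %s\n", ok(x$criterion2_ok)))
  cat(sprintf("  (iii) max regulators per gene (%d) <= M (%d): %s\n",
              x$max_regulators_per_gene, x$n_experiments, ok(x$criterion3_ok)))
  if (length(x$offending_tfs))
    cat("  offending TFs:", paste(x$offending_tfs, collapse = ", "), "\n")
  if (length(x$offending_genes))
    cat(sprintf("  offending genes: %d (e.g. %s)\n", length(x$offending_genes),
                paste(utils::head(x$offending_genes, 5), collapse = ", ")))
  invisible(x)
}

is_compliant <- function(report) {
  report$criterion1_ok && report$criterion2_ok && report$criterion3_ok
}
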