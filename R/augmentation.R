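#' Pooled variance of the row-centred expression matrix
#'
#' Subtracts each gene's mean from its row and returns the pooled
#' (population, divide by N*M) variance of all entries of the centred
#' matrix. This global variance scales the noise of the in-silico
#' replicates drawn by [augment_expression()]. Adding a per-gene constant
#' leaves the value unchanged.
#'
#' @param E expression matrix with at least 2 experiments.
#' @return A non-negative scalar.
#' @export
estimate_sigma2 <- function(E) {
  if (ncol(E) < 2L) stop("variance undefined with a single experiment")
  centred <- E - rowMeans(E)
  sum(centred^2) / length(centred)
}

#' Plan an in-silico augmentation
#'
#' Determines whether augmentation is needed and how many replicate
#' blocks to draw. Augmentation is needed when the data are
#' under-determined for the downstream stepwise regression: a gene has
#' more candidate regulators than there are experiments (compliance
#' criterion iii) or fewer than 4 experiments are available. The
#' replicate count follows the rule of thumb that the total number of
#' data columns should be approximately twice the maximal number of TFs
#' regulating a gene: 3 replicate blocks when that is required to
#' approach the target, otherwise 2.
#'
#' @param E expression matrix.
#' @param pattern the `nca_pattern` the data will be analysed with.
#' @param n_replicates optional override of the replicate-block count.
#' @return A list of class `nca_augmentation_plan` with `needed`,
#'   `n_replicates`, `sigma2`, `max_regulators` and
#'   `target_total_columns`.
#' @export
augmentation_plan <- function(E, pattern, n_replicates = NULL) {
  stopifnot(inherits(pattern, "nca_pattern"))
  M <- ncol(E)
  max_reg <- as.integer(max(rowSums(pattern$mask)))
  target <- 2L * max_reg
  needed <- max_reg > M || M < 4L
  if (is.null(n_replicates))
    n_replicates <- if (M * (1L + 2L) >= target) 2L else 3L
  total <- M * (1L + n_replicates)
  if (needed && total < target)
    nca_log("augment",
            "augmented column count %d is below the 2 x max-regulators rule of thumb (%d)",
            total, target)
  structure(list(needed = needed, n_replicates = as.integer(n_replicates),
                 sigma2 = if (M >= 2L) estimate_sigma2(E) else NA_real_,
                 max_regulators = max_reg, target_total_columns = target),
            class = "nca_augmentation_plan")
}

#' Generate in-silico replicate expression data
#'
#' Expands an expression matrix with seeded in-silico replicates so that
#' under-determined decompositions become solvable. Each log-ratio E_ij
#' is treated as the mean of a normal distribution whose variance scales
#' with its own magnitude, Var = E_ij^2 * sigma^2, where sigma^2 is the
#' pooled variance of the row-centred data ([estimate_sigma2()]). Each
#' replicate block is an independent draw from these per-cell
#' distributions; entries that are exactly zero therefore replicate as
#' exactly zero, and a zero global variance reproduces the original
#' columns.
#'
#' The replicates stabilise the decomposition numerically but do not
#' drive the final edge selection: their redundancy is eliminated by the
#' stepwise regression of the trimming stage.
#'
#' @param E expression matrix (at least 2 experiments, needed to
#'   estimate sigma^2).
#' @param n_replicates number of replicate blocks to append (2-3
#'   typical; see [augmentation_plan()]).
#' @param seed integer seed; draws are reproducible.
#' @return An expression matrix with `ncol(E) * (1 + n_replicates)`
#'   columns: the original columns first, then each replicate block with
#'   column labels suffixed `_rep<b>`.
#' @export
augment_expression <- function(E, n_replicates = 3L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  if (is.null(colnames(E))) colnames(E) <- paste0("exp", seq_len(ncol(E)))
  sigma2 <- estimate_sigma2(E)
  sdm <- abs(E) * sqrt(sigma2)
  blocks <- with_rng_seed(seed, lapply(seq_len(n_replicates), function(b) {
    R <- E + matrix(stats::rnorm(length(E)), nrow(E), ncol(E)) * sdm
    colnames(R) <- paste0(colnames(E), "_rep", b)
    R
  }))
  out <- do.call(cbind, c(list(E), blocks))
  rownames(out) <- rownames(E)
  out
}

#' Average replicate columns per condition
#'
#' Preprocessing helper for designs with measured replicates: averages
#' the columns of each condition before augmentation, mirroring the
#' common practice of building condition-level log-ratios from replicate
#' averages and then augmenting.
#'
#' @param E expression matrix.
#' @param groups factor or character vector of length `ncol(E)` giving
#'   the condition of each column.
#' @return An expression matrix with one column per condition level, in
#'   order of first appearance.
#' @export
average_replicates <- function(E, groups) {
  if (length(groups) != ncol(E))
    stop("groups must have one entry per expression column")
  groups <- factor(groups, levels = unique(as.character(groups)))
  out <- sapply(levels(groups), function(g)
    rowMeans(E[, groups == g, drop = FALSE]))
  out <- matrix(out, nrow = nrow(E),
                dimnames = list(rownames(E), levels(groups)))
  out
}
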