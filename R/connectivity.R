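#' Construct a TF-gene connectivity pattern
#'
#' The connectivity pattern is the binary zero-pattern constraint of the
#' decomposition: entry (i, j) is 1 when TF j is allowed to regulate gene
#' i. The `iteration` counter records how many trimming passes produced
#' the pattern (0 for the initial network).
#'
#' @param mask binary numeric matrix, genes x TFs.
#' @param gene_ids,tf_ids row/column labels; default to `dimnames(mask)`.
#' @param iteration non-negative integer trim-iteration counter.
#' @param validate if `TRUE` (default), require every gene row and every TF
#'   column to contain at least one edge.
#' @return An object of class `nca_pattern` with elements `mask`,
#'   `iteration`.
#' @examples
#' Z <- connectivity_pattern(matrix(c(1, 1, 0, 0, 1, 1), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("TF1", "TF2"))))
#' n_edges(Z)
#' @export
connectivity_pattern <- function(mask, gene_ids = rownames(mask),
                                 tf_ids = colnames(mask), iteration = 0L,
                                 validate = TRUE) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("connectivity mask entries must be 0 or 1")
  storage.mode(mask) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(mask)))
  if (is.null(tf_ids)) tf_ids <- paste0("TF", seq_len(ncol(mask)))
  dimnames(mask) <- list(as.character(gene_ids), as.character(tf_ids))
  if (validate) {
    orphan <- rownames(mask)[rowSums(mask) == 0]
    if (length(orphan))
      stop("gene(s) with no regulator in the pattern: ",
           paste(utils::head(orphan, 5), collapse = ", "))
    empty <- colnames(mask)[colSums(mask) == 0]
    if (length(empty))
      stop("TF(s) with an empty regulon: ", paste(empty, collapse = ", "))
  }
  structure(list(mask = mask, iteration = as.integer(iteration)),
            class = "nca_pattern")
}

#' Number of edges in a connectivity pattern
#' @param pattern an `nca_pattern`.
#' @return Integer edge count.
#' @export
n_edges <- function(pattern) {
  stopifnot(inherits(pattern, "nca_pattern"))
  as.integer(sum(pattern$mask))
}

#' Edge list of a connectivity pattern
#' @param pattern an `nca_pattern`.
#' @return A data.frame with columns `tf` and `gene`, one row per edge.
#' @export
pattern_edges <- function(pattern) {
  stopifnot(inherits(pattern, "nca_pattern"))
  idx <- which(pattern$mask == 1, arr.ind = TRUE)
  data.frame(tf = colnames(pattern$mask)[idx[, 2]],
             gene = rownames(pattern$mask)[idx[, 1]],
             stringsAsFactors = FALSE)[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' @export
print.nca_pattern <- function(x, ...) {
  cat(sprintf("TF-gene connectivity pattern: %d genes x %d TFs, %d edges (iteration %d)\n",
              nrow(x$mask), ncol(x$mask), n_edges(x), x$iteration))
  invisible(x)
}
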