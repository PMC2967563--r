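#' Construct a labelled expression matrix
#'
#' An expression matrix holds log-ratio expression values for N genes
#' (rows) across M experiments (columns). Gene identifiers must be unique;
#' rows containing missing values are dropped with a logged count, because
#' the per-gene regression model used downstream assumes complete
#' expression vectors.
#'
#' @param values numeric matrix of log-ratios, genes in rows.
#' @param gene_ids character vector of unique gene identifiers
#'   (defaults to `rownames(values)`).
#' @param experiment_ids character vector of experiment labels
#'   (defaults to `colnames(values)`).
#' @return A numeric matrix with validated dimnames.
#' @examples
#' E <- expression_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("g", 1:3), paste0("e", 1:2))))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              experiment_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one experiment")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(experiment_ids))
    experiment_ids <- paste0("exp", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  }
  dimnames(values) <- list(gene_ids, as.character(experiment_ids))
  bad <- which(rowSums(is.na(values)) > 0L)
  if (length(bad)) {
    nca_log("expression", "dropping %d gene(s) with missing values", length(bad))
    values <- values[-bad, , drop = FALSE]
    if (nrow(values) == 0L) stop("all genes dropped: every row had missing values")
  }
  values
}
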