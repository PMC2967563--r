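#' Read an expression matrix from a TSV file
#'
#' Expects a tab-separated file whose first column holds gene
#' identifiers and whose header row holds experiment labels; remaining
#' cells are decimal log-ratios. Duplicate gene identifiers and
#' non-numeric cells are rejected with the offending location; rows
#' containing missing values are dropped with a logged count.
#'
#' @param path file path.
#' @return An expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("malformed expression file (need a gene-id column plus data): ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("NA", "NaN", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at line %d, column '%s' of %s",
                 vals[bad[1, , drop = FALSE]], bad[1, 1] + 1L,
                 colnames(df)[bad[1, 2] + 1L], path))
  dimnames(num) <- list(ids, colnames(df)[-1])
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#' @param E expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(E, path) {
  df <- data.frame(gene = rownames(E), E, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-gene connectivity network from a TSV file
#'
#' Accepts either a 2-3 column edge list (`tf_id`, `gene_id`, optional
#' annotation; a header row is detected and skipped) or a dense 0/1
#' adjacency table with gene rownames and TF column labels. The format
#' is auto-detected from the column count and cell content. Edges whose
#' gene is absent from `gene_universe` are dropped with a logged count;
#' an empty intersection is an error. Gene rows are ordered per
#' `gene_universe` so the pattern aligns with the expression matrix.
#'
#' @param path file path.
#' @param gene_universe optional character vector of genes present in the
#'   expression data; the pattern is restricted and ordered to it.
#' @return An `nca_pattern`.
#' @export
read_network <- function(path, gene_universe = NULL) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) <= 3L) {
    edges <- raw
    first <- tolower(as.character(edges[1, 1:2]))
    if (any(first %in% c("tf", "tf_id", "regulator", "source")))
      edges <- edges[-1, , drop = FALSE]
    edges <- data.frame(tf = edges[[1]], gene = edges[[2]],
                        stringsAsFactors = FALSE)
  } else {
    adj <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(adj)
    if (!all(m %in% c(0, 1)))
      stop("adjacency table in ", path, " contains values other than 0/1")
    idx <- which(m == 1, arr.ind = TRUE)
    edges <- data.frame(tf = colnames(m)[idx[, 2]],
                        gene = rownames(m)[idx[, 1]],
                        stringsAsFactors = FALSE)
  }
  pattern_from_edges(edges, gene_universe)
}

#' Build a connectivity pattern from an edge data.frame
#'
#' @param edges data.frame with columns `tf` and `gene`.
#' @param gene_universe optional gene ordering/filter (see
#'   [read_network()]).
#' @return An `nca_pattern`.
#' @export
pattern_from_edges <- function(edges, gene_universe = NULL) {
  stopifnot(all(c("tf", "gene") %in% names(edges)))
  edges <- unique(edges[, c("tf", "gene")])
  if (!is.null(gene_universe)) {
    keep <- edges$gene %in% gene_universe
    if (!any(keep))
      stop("no network gene is present in the expression data")
    if (any(!keep))
      nca_log("network", "dropping %d edge(s) to genes absent from the expression data",
              sum(!keep))
    edges <- edges[keep, , drop = FALSE]
    genes <- gene_universe[gene_universe %in% edges$gene]
  } else {
    genes <- sort(unique(edges$gene))
  }
  tfs <- sort(unique(edges$tf))
  mask <- matrix(0, length(genes), length(tfs),
                 dimnames = list(genes, tfs))
  mask[cbind(match(edges$gene, genes), match(edges$tf, tfs))] <- 1
  connectivity_pattern(mask)
}

#' Write a connectivity pattern as an edge list
#' @param pattern an `nca_pattern`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(pattern, path) {
  utils::write.table(pattern_edges(pattern), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a decomposition (A, P and a JSON sidecar)
#'
#' Writes `A.tsv` (control strengths) and `P.tsv` (TFA profiles) with
#' labels, plus `decomposition.json` recording the residual norm, seed,
#' solver options and normalisation factors.
#'
#' @param dec an `nca_decomposition`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(dec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(gene = rownames(dec$A), dec$A,
                                check.names = FALSE),
                     file.path(dir, "A.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(tf = rownames(dec$P), dec$P,
                                check.names = FALSE),
                     file.path(dir, "P.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(residual_norm = dec$residual_norm,
                            converged = dec$converged,
                            n_outer_iterations = dec$n_outer_iterations,
                            seed = dec$seed,
                            options = unclass(dec$options),
                            scale_record = as.list(dec$scale_record)),
                       file.path(dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
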