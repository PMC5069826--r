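#' Per-sample composite signature score
#'
#' The sample mean score: for each sample, the arithmetic mean of the
#' gene-level expression values over the signature genes. The score is
#' invariant to gene ordering and to non-signature genes in the matrix,
#' and shifts by exactly `c` when `c` is added to every signature-gene
#' value of a sample.
#'
#' Missing gene values are excluded from the sample's mean with a
#' warning; a sample with all signature values missing is an error, as
#' is a signature gene absent from the matrix (use
#' [restrict_signature()] first to drop unavailable genes explicitly).
#'
#' @param gene_matrix A gene-level [expression_matrix()] whose feature
#'   ids are gene symbols.
#' @param signature Character vector of signature gene symbols.
#' @param dataset_label Free-text label carried into the result (e.g.
#'   `"Affy_FF"`).
#' @return A list of class `"sample_scores"`: `scores` (named numeric,
#'   one per sample), `dataset_label`, `gene_set_size`, `genes_used`.
#' @export
signature_score <- function(gene_matrix, signature,
                            dataset_label = "dataset") {
  absent <- setdiff(signature, feature_ids(gene_matrix))
  if (length(absent))
    stop("signature gene(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  v <- gene_matrix$values[signature, , drop = FALSE]
  n_missing <- colSums(is.na(v))
  if (any(n_missing == length(signature)))
    stop("sample(s) with all signature values missing: ",
         paste(colnames(v)[n_missing == length(signature)],
               collapse = ", "), call. = FALSE)
  if (any(n_missing > 0))
    warning("missing signature values excluded from the mean for sample(s): ",
            paste(colnames(v)[n_missing > 0], collapse = ", "),
            call. = FALSE)
  structure(list(scores = colMeans(v, na.rm = TRUE),
                 dataset_label = dataset_label,
                 gene_set_size = length(signature),
                 genes_used = signature),
            class = "sample_scores")
}

#' @export
print.sample_scores <- function(x, ...) {
  cat(sprintf("sample_scores [%s]: %d samples, %d-gene signature\n",
              x$dataset_label, length(x$scores), x$gene_set_size))
  print(summary(unname(x$scores)))
  invisible(x)
}

#' Write per-sample scores to TSV
#'
#' Columns `sample_id`, `score`; the dataset label and gene count go in
#' a `#`-prefixed header comment line.
#'
#' @param x A [signature_score()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_scores <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dataset=%s genes=%d samples=%d",
                     x$dataset_label, x$gene_set_size, length(x$scores)),
             con)
  utils::write.table(
    data.frame(sample_id = names(x$scores), score = unname(x$scores)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
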