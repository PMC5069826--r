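#' Expression matrix container
#'
#' A light S3 container for a features-by-samples numeric expression
#' matrix together with the metadata every stage of the workflow needs:
#' the measurement scale and the feature-to-gene mapping (several
#' platform features -- probes or probesets -- may map to one gene;
#' when features already are genes the map is the identity).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row and column names are required and must be unique; `NA` entries
#'   are allowed (they denote missing measurements).
#' @param scale Measurement scale, one of `"log2"`, `"count"`,
#'   `"fpkm"`, `"zscore"`, `"median_centered"`. Count- and FPKM-scale
#'   values must be non-negative.
#' @param feature_to_gene Named character vector mapping every feature
#'   id (names) to a gene symbol (values). Defaults to the identity
#'   map on the row names.
#'
#' @return An object of class `"expression_matrix"`: a list with
#'   elements `values`, `scale`, `feature_to_gene`.
#' @export
expression_matrix <- function(values, scale = c("log2", "count", "fpkm",
                                                "zscore", "median_centered"),
                              feature_to_gene = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  # zero-extent dimensions cannot carry names in R; only require names
  # where there is something to name
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("'values' must have feature (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (scale %in% c("count", "fpkm") && any(values < 0, na.rm = TRUE))
    stop(scale, "-scale values must be non-negative", call. = FALSE)
  if (nrow(values) == 0L) {
    feature_to_gene <- stats::setNames(character(0), character(0))
  } else if (is.null(feature_to_gene)) {
    feature_to_gene <- stats::setNames(rownames(values), rownames(values))
  } else {
    if (is.null(names(feature_to_gene)) ||
        !all(rownames(values) %in% names(feature_to_gene)))
      stop("'feature_to_gene' must be named and cover every feature",
           call. = FALSE)
    feature_to_gene <- feature_to_gene[rownames(values)]
  }
  structure(list(values = values, scale = scale,
                 feature_to_gene = feature_to_gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  genes: %d  missing entries: %d\n",
              length(unique(x$feature_to_gene)), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids  <- function(x) colnames(x$values)

# Subset an expression_matrix by feature and/or sample ids, keeping the
# mapping in step.
subset_em <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss))
      stop("features not present: ", paste(miss, collapse = ", "),
           call. = FALSE)
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss))
      stop("samples not present: ", paste(miss, collapse = ", "),
           call. = FALSE)
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, scale = x$scale,
                    feature_to_gene = x$feature_to_gene[rownames(v)])
}

#' Write an expression matrix to a tab-separated file
#'
#' The format is one header row of sample ids, feature ids in the first
#' column (`feature_id`), tab-separated, UTF-8. It round-trips through
#' [read_expression_matrix()].
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  # 17 significant digits: doubles round-trip exactly through text
  chr <- apply(x$values, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(x$values),
                                     dimnames = dimnames(x$values))
  df <- data.frame(feature_id = feature_ids(x), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("failed to write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read an expression matrix from a tab-separated file
#'
#' @param path File written by [write_expression_matrix()] (or any TSV
#'   with feature ids in the first column and sample ids as header).
#' @param scale Measurement scale of the stored values.
#' @param feature_to_gene Optional feature-to-gene map; identity by
#'   default.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = "log2",
                                   feature_to_gene = NULL) {
  if (!file.exists(path))
    stop("no such file: '", path, "'", call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = NA)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, scale = scale, feature_to_gene = feature_to_gene)
}
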