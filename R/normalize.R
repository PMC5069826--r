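#' Housekeeping geometric-mean normalization for count data
#'
#' The reference-gene normalization used for NanoString-style counts:
#' the geometric mean of the housekeeping genes is computed for each
#' sample, and the per-sample normalization factor is the across-sample
#' average of those geometric means divided by the sample's own
#' geometric mean. Every count in the sample is multiplied by its
#' factor. After normalization the housekeeping geometric mean is, by
#' construction, identical across samples (the method's fixed point),
#' and within-sample rank order is preserved (positive scalar
#' multiplication). Normalized counts are not re-rounded to integers.
#'
#' @param counts A count-scale [expression_matrix()] whose features are
#'   gene symbols and which contains every housekeeping gene.
#' @param hk_genes Character vector of housekeeping gene symbols;
#'   defaults to the packaged 11-gene panel.
#' @return A list with `matrix` (the normalized [expression_matrix()],
#'   still count scale) and `factors` (a list with `per_sample_factor`,
#'   a named positive vector, and `overall_mean`, the across-sample
#'   average housekeeping geometric mean) for audit.
#' @export
housekeeping_normalize <- function(counts, hk_genes = housekeeping_genes()) {
  v <- counts$values
  missing_hk <- setdiff(hk_genes, rownames(v))
  if (length(missing_hk))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing_hk, collapse = ", "), call. = FALSE)
  hk <- v[hk_genes, , drop = FALSE]
  bad <- which(!(hk > 0), arr.ind = TRUE)  # catches NA, 0, negative
  if (nrow(bad))
    stop("non-positive housekeeping count(s): ",
         paste(sprintf("%s in sample %s",
                       rownames(hk)[bad[, 1]], colnames(hk)[bad[, 2]]),
               collapse = "; "), call. = FALSE)
  geo <- exp(colMeans(log(hk)))
  overall <- mean(geo)
  f <- overall / geo
  out <- sweep(v, 2, f, `*`)
  list(matrix = expression_matrix(out, scale = counts$scale,
                                  feature_to_gene = counts$feature_to_gene),
       factors = list(per_sample_factor = f, overall_mean = overall))
}

#' Per-sample median normalization
#'
#' Subtracts each sample's median (over its non-missing values) from
#' every value in the sample, so each sample column has median exactly
#' zero. Re-application changes nothing (idempotence). Missing entries
#' stay missing and are excluded from the median.
#'
#' @param counts An [expression_matrix()] on any scale.
#' @return A median-centered [expression_matrix()].
#' @export
median_normalize <- function(counts) {
  v <- counts$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing))
    stop("sample(s) with no non-missing values: ",
         paste(colnames(v)[all_missing], collapse = ", "), call. = FALSE)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  expression_matrix(sweep(v, 2, med, `-`), scale = "median_centered",
                    feature_to_gene = counts$feature_to_gene)
}

#' Log2 transformation and per-feature z-score normalization
#'
#' For FPKM-scale input, computes `y = log2(x + pseudocount)` and then
#' standardizes each feature row to mean 0 and sample standard
#' deviation 1 (n - 1 denominator) across samples. Features with zero
#' variance after the log transform cannot be standardized and are
#' excluded with a warning naming them. If the input is already on the
#' z-score scale the log step is skipped, so the operation is
#' idempotent.
#'
#' @param fpkm An [expression_matrix()] with non-negative FPKM-scale
#'   values (or a z-score-scale matrix, which is only re-standardized).
#' @param pseudocount Positive value added before the log2 transform;
#'   default 1.
#' @return A z-score-scale [expression_matrix()].
#' @export
log2_zscore_normalize <- function(fpkm, pseudocount = 1) {
  if (pseudocount <= 0)
    stop("'pseudocount' must be positive", call. = FALSE)
  v <- fpkm$values
  if (fpkm$scale != "zscore") {
    if (any(v < 0, na.rm = TRUE))
      stop("FPKM values must be non-negative", call. = FALSE)
    v <- log2(v + pseudocount)
  }
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  flat <- !is.na(sds) & sds == 0
  if (any(flat)) {
    warning("excluding zero-variance feature(s): ",
            paste(rownames(v)[flat], collapse = ", "), call. = FALSE)
    v <- v[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  z <- (v - rowMeans(v, na.rm = TRUE)) / sds
  expression_matrix(z, scale = "zscore",
                    feature_to_gene = fpkm$feature_to_gene[rownames(z)])
}
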