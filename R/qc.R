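#' Sample-quality PCA of an expression matrix
#'
#' Flags presumptively degraded samples by principal-component
#' analysis of the full feature matrix: each feature is centered
#' across samples, the sample-by-sample covariance matrix over
#' features is formed (n_features - 1 divisor), and its top two unit
#' eigenvectors give the per-sample PC1 and PC2 scores. Degraded FFPE
#' samples, whose signal is attenuated toward background, separate on
#' PC1.
#'
#' Eigenvector signs are indeterminate, so each component is oriented
#' so that its Pearson correlation with per-sample mean expression is
#' non-negative (ties: entry sum non-negative); low-quality,
#' low-signal samples then land at low PC1, and a fixed threshold on
#' the unit-norm entries (default -0.10) flags them. The applied
#' orientation is recorded in the result for audit.
#'
#' @param matrix An [expression_matrix()] with no missing values, at
#'   least 3 samples and 2 features.
#' @param threshold PC1 flagging threshold (strict `<`). Default -0.10.
#' @return A list of class `"qc_result"`: `pc1`, `pc2` (named unit
#'   vectors), `eigenvalues` (first two), `var_fraction` (their share
#'   of total variance), `threshold`, `flagged` (sample ids with
#'   `pc1 < threshold`), `sign_convention`.
#' @export
pca_sample_scores <- function(matrix, threshold = -0.10) {
  v <- matrix$values
  if (anyNA(v))
    stop("matrix contains missing values; impute or drop upstream",
         call. = FALSE)
  if (ncol(v) < 3L || nrow(v) < 2L)
    stop("need >= 3 samples and >= 2 features", call. = FALSE)
  centered <- v - rowMeans(v)
  C <- stats::cov(centered)  # samples as variables, features as observations
  if (max(abs(C)) < .Machine$double.eps * 100)
    stop("degenerate input: all samples identical", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  sample_means <- colMeans(v)
  orient <- function(vec) {
    r <- suppressWarnings(stats::cor(vec, sample_means))
    s <- if (is.na(r) || r == 0) {
      if (sum(vec) >= 0) 1 else -1
    } else if (r > 0) 1 else -1
    list(vec = s * vec, flipped = s < 0)
  }
  o1 <- orient(e$vectors[, 1])
  o2 <- orient(e$vectors[, 2])
  pc1 <- stats::setNames(o1$vec, colnames(v))
  pc2 <- stats::setNames(o2$vec, colnames(v))
  total <- sum(pmax(e$values, 0))
  structure(list(
    pc1 = pc1, pc2 = pc2,
    eigenvalues = e$values[1:2],
    var_fraction = e$values[1:2] / total,
    threshold = threshold,
    flagged = names(pc1)[pc1 < threshold],
    sign_convention = c(
      rule = "orient each PC to correlate non-negatively with per-sample mean expression (tie: non-negative entry sum)",
      pc1 = if (o1$flipped) "flipped" else "as_computed",
      pc2 = if (o2$flipped) "flipped" else "as_computed")),
    class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "qc_result: %d samples; PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
    length(x$pc1), 100 * x$var_fraction[1], 100 * x$var_fraction[2]))
  cat(sprintf("  %d sample(s) flagged at PC1 < %g\n",
              length(x$flagged), x$threshold))
  invisible(x)
}

#' Flag outlier samples by PC1 threshold
#'
#' Returns exactly the samples whose PC1 entry is strictly below the
#' threshold.
#'
#' @param qc A [pca_sample_scores()] result.
#' @param threshold PC1 threshold (strict `<`).
#' @return Character vector of flagged sample ids.
#' @export
flag_outliers <- function(qc, threshold = qc$threshold) {
  names(qc$pc1)[qc$pc1 < threshold]
}

#' Write a QC report (and PC2-vs-PC1 scatter data) to TSV
#'
#' One row per sample with columns `sample_id`, `pc1`, `pc2`,
#' `flagged`; directly plottable as a PC2-vs-PC1 scatter.
#'
#' @param qc A [pca_sample_scores()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  df <- data.frame(sample_id = names(qc$pc1),
                   pc1 = unname(qc$pc1), pc2 = unname(qc$pc2),
                   flagged = names(qc$pc1) %in% qc$flagged)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
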