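#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks both vectors with average ranks for ties, takes the Pearson
#' correlation of the ranks, and computes a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (the convention of common statistical packages
#' at the sample sizes this workflow sees). At `rho = +/-1` the p-value
#' is reported as 0. Pairs with a missing member are dropped first.
#'
#' @param x,y Numeric vectors, paired; at least 3 complete pairs, each
#'   with non-zero variance.
#' @return A list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Pairwise Spearman concordance among score sets
#'
#' Computes the Spearman correlation (and p-value) for every unordered
#' pair of score sets, pairing samples by id on the intersection of
#' the two sets' sample ids minus `exclude`. Six datasets yield the 15
#' possible pairs. A pair with insufficient overlap (fewer than 3
#' shared samples, or zero variance) is reported as `NA`, never
#' fabricated.
#'
#' @param score_sets List of [signature_score()] results with distinct
#'   `dataset_label`s.
#' @param exclude Sample ids to drop from every pair (e.g. PCA-flagged
#'   outliers).
#' @return A list of class `"concordance_table"`: `labels`, symmetric
#'   matrices `rho` (unit diagonal), `p` (zero diagonal) and `n_used`,
#'   plus `exclude`.
#' @export
pairwise_concordance <- function(score_sets, exclude = character(0)) {
  if (length(score_sets) < 2)
    stop("need at least two score sets", call. = FALSE)
  labels <- vapply(score_sets, function(s) s$dataset_label, character(1))
  if (anyDuplicated(labels))
    stop("dataset labels must be distinct", call. = FALSE)
  k <- length(labels)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    diag(nmat)[i] <- length(setdiff(names(score_sets[[i]]$scores), exclude))
    for (j in seq_len(k)) {
      if (j <= i) next
      common <- setdiff(intersect(names(score_sets[[i]]$scores),
                                  names(score_sets[[j]]$scores)), exclude)
      res <- tryCatch(
        spearman_cor(score_sets[[i]]$scores[common],
                     score_sets[[j]]$scores[common]),
        error = function(e) list(rho = NA_real_, p = NA_real_,
                                 n = length(common)))
      rho[i, j] <- rho[j, i] <- res$rho
      p[i, j] <- p[j, i] <- res$p
      nmat[i, j] <- nmat[j, i] <- res$n
    }
  }
  structure(list(labels = labels, rho = rho, p = p, n_used = nmat,
                 exclude = exclude),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, digits = 3, ...) {
  cat(sprintf("concordance_table: %d datasets, %d pairs (n excluded: %d)\n",
              length(x$labels), choose(length(x$labels), 2),
              length(x$exclude)))
  disp <- matrix("", length(x$labels), length(x$labels),
                 dimnames = dimnames(x$rho))
  for (i in seq_along(x$labels))
    for (j in seq_along(x$labels))
      disp[i, j] <- if (i == j) "1" else if (is.na(x$rho[i, j])) "NA" else
        sprintf("%.*f (%.4g)", digits, x$rho[i, j], x$p[i, j])
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a concordance table to TSV
#'
#' Writes a machine-readable long format (`dataset_a`, `dataset_b`,
#' `rho`, `p`, `n_used`) and, alongside it at `<path>.display.tsv`, a
#' square "rho (p)" display table.
#'
#' @param x A [pairwise_concordance()] result.
#' @param path Output path for the long-format table.
#' @return `path`, invisibly.
#' @export
write_concordance_table <- function(x, path) {
  k <- length(x$labels)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  long <- data.frame(dataset_a = x$labels[idx[, 1]],
                     dataset_b = x$labels[idx[, 2]],
                     rho = x$rho[idx], p = x$p[idx], n_used = x$n_used[idx])
  long <- long[order(long$dataset_a, long$dataset_b), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  disp <- matrix("", k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    disp[i, j] <- if (i == j) "1" else if (is.na(x$rho[i, j])) "NA" else
      sprintf("%.3f (%.4g)", x$rho[i, j], x$p[i, j])
  ddf <- data.frame(dataset = x$labels, disp)
  names(ddf) <- c("dataset", x$labels)
  utils::write.table(ddf, paste0(path, ".display.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by full hypergeometric enumeration:
#' the sum of the probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' 1e-7 relative slack against floating-point ties), the
#' sum-of-small-probabilities convention.
#'
#' @param table 2x2 matrix of non-negative integer counts, total >= 1.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop("'table' must be a 2x2 matrix", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(table) < 1) stop("table total must be >= 1", call. = FALSE)
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  kk <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(kk, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
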