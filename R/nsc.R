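#' Train a nearest shrunken centroids (PAM) classifier
#'
#' Fits the shrunken-centroid model: with overall centroid `xbar_j`,
#' class centroids `xbar_kj`, pooled within-class standard deviation
#' `s_j`, fudge constant `s0 = median_j(s_j)` and
#' `m_k = sqrt(1/n_k - 1/n)`, the standardized class offsets are
#' `d_kj = (xbar_kj - xbar_j) / (m_k * (s_j + s0))`. Soft thresholding
#' `d'_kj = sign(d_kj) * max(|d_kj| - delta, 0)` shrinks the offsets
#' toward zero, and the shrunken centroids are
#' `xbar'_kj = xbar_j + m_k * (s_j + s0) * d'_kj`. Genes with every
#' `d'_kj = 0` no longer influence classification, so shrinkage
#' performs embedded gene selection; `delta = 0` reproduces the plain
#' class centroids.
#'
#' @param x Numeric gene-by-sample matrix with row (gene) and column
#'   (sample) names; no missing values.
#' @param y Class labels, one per sample. Coerced to factor; the level
#'   order fixes the class order (used for prediction tie-breaks).
#'   Every class needs at least 2 samples.
#' @param delta Non-negative shrinkage threshold.
#' @param priors Named class prior probabilities summing to 1; default
#'   the observed class proportions.
#' @param offset_variant `"minus"` (default) uses
#'   `m_k = sqrt(1/n_k - 1/n)`, the variance of the centroid contrast
#'   `xbar_k - xbar`; `"plus"` uses the `sqrt(1/n_k + 1/n)` variant
#'   found in parts of the literature.
#' @return An object of class `"nsc"`: a list with `classes`, `xbar`,
#'   `centroids` (gene x class), `s`, `s0`, `m_k`, `priors`, `delta`,
#'   `d`, `d_shrunk`, `shrunken_centroids`, `surviving_genes`,
#'   `offset_variant`.
#' @seealso [predict.nsc()], [nsc_loocv()]
#' @export
nsc_train <- function(x, y, delta = 0, priors = NULL,
                      offset_variant = c("minus", "plus")) {
  offset_variant <- match.arg(offset_variant)
  if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)
  if (!is.matrix(x) || anyNA(x))
    stop("'x' must be a complete numeric matrix", call. = FALSE)
  y <- droplevels(as.factor(y))
  if (length(y) != ncol(x))
    stop("length(y) must equal ncol(x)", call. = FALSE)
  classes <- levels(y)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  n_k <- table(y)
  if (any(n_k < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(classes[n_k < 2], collapse = ", "), call. = FALSE)
  n <- ncol(x)
  K <- length(classes)

  xbar <- rowMeans(x)
  centroids <- matrix(0, nrow(x), K, dimnames = list(rownames(x), classes))
  for (k in classes)
    centroids[, k] <- rowMeans(x[, y == k, drop = FALSE])
  # pooled within-class sd, n - K denominator
  ss <- 0
  for (k in classes) {
    xk <- x[, y == k, drop = FALSE]
    ss <- ss + rowSums((xk - centroids[, k])^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  m_k <- if (offset_variant == "minus") sqrt(1 / as.numeric(n_k) - 1 / n)
         else sqrt(1 / as.numeric(n_k) + 1 / n)
  names(m_k) <- classes

  if (is.null(priors)) {
    priors <- as.numeric(n_k) / n
    names(priors) <- classes
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), classes))
      stop("'priors' must be named with the class labels", call. = FALSE)
    priors <- priors[classes]
    if (abs(sum(priors) - 1) > 1e-8)
      stop("'priors' must sum to 1", call. = FALSE)
  }

  d <- sweep(centroids - xbar, 1, s + s0, `/`)
  d <- sweep(d, 2, m_k, `/`)
  fit <- structure(list(classes = classes, xbar = xbar,
                        centroids = centroids, s = s, s0 = s0, m_k = m_k,
                        priors = priors, d = d,
                        offset_variant = offset_variant,
                        n = n, n_k = as.numeric(n_k)),
                   class = "nsc")
  nsc_shrink(fit, delta)
}

# Apply soft thresholding at a given delta to an already-fitted model;
# everything that depends on delta is recomputed here so LOOCV can walk
# a threshold grid from one fold fit.
nsc_shrink <- function(fit, delta) {
  dprime <- sign(fit$d) * pmax(abs(fit$d) - delta, 0)
  scale <- outer(fit$s + fit$s0, fit$m_k)
  fit$delta <- delta
  fit$d_shrunk <- dprime
  fit$shrunken_centroids <- fit$xbar + scale * dprime
  fit$surviving_genes <- rownames(fit$d)[rowSums(dprime != 0) > 0]
  fit
}

#' @export
print.nsc <- function(x, ...) {
  cat(sprintf(
    "nsc: %d-class shrunken-centroid model, %d genes (%d surviving at delta = %g)\n",
    length(x$classes), nrow(x$d), length(x$surviving_genes), x$delta))
  cat("  classes:", paste(sprintf("%s (prior %.3f)", x$classes, x$priors),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.nsc <- function(object, ...) {
  print(object)
  if (length(object$surviving_genes)) {
    cat("surviving genes:\n")
    print(object$surviving_genes)
  }
  invisible(object)
}

#' @export
coef.nsc <- function(object, ...) object$d_shrunk

#' Predict class membership with a shrunken-centroid model
#'
#' Uses the discriminant
#' `delta_k(x) = sum_j (x_j - xbar'_kj)^2 / (s_j + s0)^2 - 2 log pi_k`
#' over the model genes and predicts the class minimizing it; an exact
#' tie goes to the first class in the model's class order.
#'
#' @param object An [nsc_train()] fit.
#' @param newdata Named numeric vector (one sample) or gene-by-sample
#'   matrix covering every model gene.
#' @param ... Unused.
#' @return A list with `class` (character vector, one per sample) and
#'   `scores` (sample-by-class discriminant matrix).
#' @export
predict.nsc <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- cbind(sample = newdata)
  genes <- rownames(object$d)
  missing <- setdiff(genes, rownames(newdata))
  if (length(missing))
    stop("gene(s) missing from newdata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  newdata <- newdata[genes, , drop = FALSE]
  denom <- (object$s + object$s0)^2
  scores <- vapply(object$classes, function(k) {
    colSums((newdata - object$shrunken_centroids[, k])^2 / denom) -
      2 * log(object$priors[k])
  }, numeric(ncol(newdata)))
  if (ncol(newdata) == 1L) scores <- matrix(scores, nrow = 1,
                                            dimnames = list(colnames(newdata),
                                                            object$classes))
  # ties resolved toward the first declared class
  cls <- object$classes[apply(scores, 1, which.min)]
  list(class = cls, scores = scores)
}

#' Leave-one-out cross-validated shrunken-centroid model selection
#'
#' For each held-out sample and each threshold on the grid the entire
#' model-building process is repeated on the remaining samples --
#' centroids, pooled standard deviations, the fudge constant and the
#' soft-thresholded gene selection are all recomputed per fold (full
#' nesting) -- and the held-out sample is predicted. The chosen
#' threshold minimizes the LOOCV misclassification fraction, ties
#' broken toward the largest threshold (the most parsimonious model),
#' and the final model is refit on all samples at that threshold.
#' Sensitivity (predicted-positive fraction among true positives) and
#' specificity are computed from the chosen-threshold LOOCV
#' predictions.
#'
#' @param x Gene-by-sample matrix; at least 4 samples.
#' @param y Class labels; every fold must leave every class with at
#'   least 2 training samples.
#' @param delta_grid Thresholds to evaluate; default `n_delta` evenly
#'   spaced values from 0 to the largest `|d_kj|` on the full data.
#' @param n_delta Grid size when `delta_grid` is `NULL`. Default 30.
#' @param priors,offset_variant Passed to [nsc_train()].
#' @param positive_class Positive class for sensitivity/specificity;
#'   default `"MUT"` when present, else the first class level.
#' @return An object of class `"nsc_cv"`: `delta_grid`, `errors`
#'   (per-threshold LOOCV error), `chosen_delta`, `error_rate`,
#'   `predictions` (per-fold, all thresholds), `chosen_predictions`,
#'   `truth`, `sensitivity`, `specificity`, `sens_counts`,
#'   `spec_counts`, `positive_class`, `surviving_genes`, `final_model`.
#' @export
nsc_loocv <- function(x, y, delta_grid = NULL, n_delta = 30L,
                      priors = NULL, offset_variant = "minus",
                      positive_class = NULL) {
  y <- droplevels(as.factor(y))
  n <- ncol(x)
  if (n < 4) stop("need at least 4 samples for LOOCV", call. = FALSE)
  full <- nsc_train(x, y, delta = 0, priors = priors,
                    offset_variant = offset_variant)
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(full$d)), length.out = n_delta)
  if (!length(delta_grid)) stop("empty delta grid", call. = FALSE)

  preds <- matrix(NA_character_, n, length(delta_grid),
                  dimnames = list(colnames(x), NULL))
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (length(levels(ytr)) < length(levels(y)) || any(table(ytr) < 2))
      stop("fold ", i, " leaves a class with fewer than 2 training samples",
           call. = FALSE)
    fold <- nsc_train(x[, -i, drop = FALSE], ytr, delta = 0,
                      priors = priors, offset_variant = offset_variant)
    xi <- x[, i]
    for (g in seq_along(delta_grid))
      preds[i, g] <- predict(nsc_shrink(fold, delta_grid[g]), xi)$class
  }
  truth <- as.character(y)
  errors <- colMeans(preds != truth)
  best <- which(errors == min(errors))
  chosen_idx <- best[which.max(delta_grid[best])]
  chosen <- delta_grid[chosen_idx]
  chosen_preds <- stats::setNames(preds[, chosen_idx], colnames(x))

  if (is.null(positive_class))
    positive_class <- if ("MUT" %in% levels(y)) "MUT" else levels(y)[1]
  pos <- truth == positive_class
  sens_counts <- c(correct = sum(chosen_preds[pos] == positive_class),
                   total = sum(pos))
  spec_counts <- c(correct = sum(chosen_preds[!pos] != positive_class),
                   total = sum(!pos))
  final <- nsc_shrink(full, chosen)
  structure(list(delta_grid = delta_grid, errors = errors,
                 chosen_delta = chosen, error_rate = errors[chosen_idx],
                 predictions = preds, chosen_predictions = chosen_preds,
                 truth = stats::setNames(truth, colnames(x)),
                 sensitivity = sens_counts[["correct"]] / sens_counts[["total"]],
                 specificity = spec_counts[["correct"]] / spec_counts[["total"]],
                 sens_counts = sens_counts, spec_counts = spec_counts,
                 positive_class = positive_class,
                 surviving_genes = final$surviving_genes,
                 final_model = final),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("nsc_cv: LOOCV over %d thresholds, chosen delta = %.4g\n",
              length(x$delta_grid), x$chosen_delta))
  cat(sprintf("  error rate %.0f%%  sensitivity %.3f = %d/%d  specificity %.3f = %d/%d (positive: %s)\n",
              100 * x$error_rate,
              x$sensitivity, x$sens_counts[["correct"]],
              x$sens_counts[["total"]],
              x$specificity, x$spec_counts[["correct"]],
              x$spec_counts[["total"]], x$positive_class))
  cat(sprintf("  %d surviving gene(s): %s\n", length(x$surviving_genes),
              paste(x$surviving_genes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.nsc_cv <- function(object, ...) {
  print(object)
  cat("per-threshold LOOCV error:\n")
  print(data.frame(delta = object$delta_grid, error = object$errors),
        row.names = FALSE)
  invisible(object)
}

#' Write a cross-validation report to TSV
#'
#' Writes the per-threshold error grid plus a `#`-prefixed summary
#' header with the chosen threshold, error rate and the
#' sensitivity/specificity quotients (e.g. `0.704 = 19/27`).
#'
#' @param x An [nsc_loocv()] result.
#' @param path Output path.
#' @param label Dataset label for the header.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(x, path, label = "dataset") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dataset=%s positive_class=%s", label, x$positive_class),
    sprintf("# chosen_delta=%.10g error_rate=%.10g", x$chosen_delta,
            x$error_rate),
    sprintf("# sensitivity %.3f = %d/%d", x$sensitivity,
            x$sens_counts[["correct"]], x$sens_counts[["total"]]),
    sprintf("# specificity %.3f = %d/%d", x$specificity,
            x$spec_counts[["correct"]], x$spec_counts[["total"]]),
    sprintf("# surviving_genes=%s", paste(x$surviving_genes,
                                          collapse = ","))),
    con)
  utils::write.table(data.frame(delta = x$delta_grid, error = x$errors),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
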