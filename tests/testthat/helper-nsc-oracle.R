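# Independent brute-force shrunken-centroid oracle: naive loops over
# genes, classes and samples, recomputing every quantity from its
# definition. Deliberately shares no code with the package.

oracle_nsc <- function(x, y, delta, priors = NULL) {
  y <- as.factor(y)
  classes <- levels(y)
  n <- ncol(x); G <- nrow(x); K <- length(classes)

  xbar <- numeric(G)
  for (j in seq_len(G)) xbar[j] <- sum(x[j, ]) / n

  cent <- matrix(0, G, K, dimnames = list(rownames(x), classes))
  nk <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(y == classes[k])
    nk[k] <- length(idx)
    for (j in seq_len(G)) cent[j, k] <- sum(x[j, idx]) / nk[k]
  }

  s <- numeric(G)
  for (j in seq_len(G)) {
    ss <- 0
    for (k in seq_len(K))
      for (i in which(y == classes[k]))
        ss <- ss + (x[j, i] - cent[j, k])^2
    s[j] <- sqrt(ss / (n - K))
  }
  s0 <- median(s)
  if (is.null(priors)) priors <- nk / n
  mk <- numeric(K)
  for (k in seq_len(K)) mk[k] <- sqrt(1 / nk[k] - 1 / n)

  d <- dprime <- matrix(0, G, K, dimnames = list(rownames(x), classes))
  for (j in seq_len(G)) for (k in seq_len(K)) {
    d[j, k] <- (cent[j, k] - xbar[j]) / (mk[k] * (s[j] + s0))
    dprime[j, k] <- sign(d[j, k]) * max(abs(d[j, k]) - delta, 0)
  }
  shrunk <- matrix(0, G, K, dimnames = list(rownames(x), classes))
  for (j in seq_len(G)) for (k in seq_len(K))
    shrunk[j, k] <- xbar[j] + mk[k] * (s[j] + s0) * dprime[j, k]

  surviving <- character(0)
  for (j in seq_len(G))
    if (any(dprime[j, ] != 0)) surviving <- c(surviving, rownames(x)[j])

  predict_one <- function(xnew) {
    disc <- numeric(K)
    for (k in seq_len(K)) {
      acc <- 0
      for (j in seq_len(G))
        acc <- acc + (xnew[j] - shrunk[j, k])^2 / (s[j] + s0)^2
      disc[k] <- acc - 2 * log(priors[k])
    }
    classes[which.min(disc)]
  }

  list(xbar = xbar, centroids = cent, s = s, s0 = s0, d = d,
       dprime = dprime, shrunken_centroids = shrunk,
       surviving = surviving, predict_one = predict_one)
}

# Plain standardized nearest-centroid rule (no shrinkage machinery):
# an independent check of the delta = 0 decision rule.
plain_standardized_centroid_predict <- function(x, y, xnew, priors = NULL) {
  y <- as.factor(y)
  classes <- levels(y)
  cent <- sapply(classes, function(k) rowMeans(x[, y == k, drop = FALSE]))
  nk <- table(y)
  s <- sqrt(Reduce(`+`, lapply(classes, function(k) {
    xk <- x[, y == k, drop = FALSE]
    rowSums((xk - rowMeans(xk))^2)
  })) / (ncol(x) - length(classes)))
  s0 <- median(s)
  if (is.null(priors)) priors <- as.numeric(nk) / ncol(x)
  disc <- sapply(seq_along(classes), function(k)
    sum((xnew - cent[, k])^2 / (s + s0)^2) - 2 * log(priors[k]))
  classes[which.min(disc)]
}

# Genes whose |d| sits numerically on the threshold: their survival is
# decided by ~1e-16 rounding, so two correct implementations may
# legitimately disagree about them.
borderline_genes <- function(d, delta, tol = 1e-9) {
  rownames(d)[apply(abs(abs(d) - delta) < tol, 1, any)]
}

random_nsc_instance <- function(seed) {
  set.seed(seed)
  G <- sample(3:20, 1)
  n1 <- sample(4:15, 1); n2 <- sample(4:15, 1)
  x <- matrix(rnorm(G * (n1 + n2)), G, n1 + n2,
              dimnames = list(sprintf("g%02d", seq_len(G)),
                              sprintf("s%02d", seq_len(n1 + n2))))
  shift <- sample(seq_len(G), max(1, G %/% 3))
  y <- factor(c(rep("A", n1), rep("B", n2)))
  x[shift, y == "A"] <- x[shift, y == "A"] + runif(1, 0.5, 2)
  list(x = x, y = y)
}
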