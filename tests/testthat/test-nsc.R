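test_that("single-gene hand computation matches the training formulas", {
  x <- toy_matrix(matrix(c(0, 2, 4, 6), 1, 4), features = "g",
                  samples = paste0("s", 1:4))
  y <- factor(c("A", "A", "B", "B"))
  fit <- nsc_train(x, y, delta = 0)
  # xbar 3; centroids 1 and 5; pooled sd sqrt(((0-1)^2+(2-1)^2+(4-5)^2+(6-5)^2)/2) = sqrt(2)
  expect_equal(unname(fit$xbar), 3)
  expect_equal(unname(fit$centroids["g", ]), c(1, 5))
  expect_equal(unname(fit$s), sqrt(2))
  expect_equal(fit$s0, sqrt(2))  # median of a single gene
  m_k <- sqrt(1 / 2 - 1 / 4)
  expect_equal(unname(fit$m_k), rep(m_k, 2))
  expect_equal(unname(fit$d["g", ]),
               c(-2, 2) / (m_k * 2 * sqrt(2)), tolerance = 1e-12)
})

test_that("delta 0 keeps class centroids; total shrinkage collapses them", {
  set.seed(40)
  inst <- random_nsc_instance(1)
  fit0 <- nsc_train(inst$x, inst$y, delta = 0)
  expect_equal(fit0$shrunken_centroids, fit0$centroids, tolerance = 1e-12)
  expect_identical(fit0$surviving_genes, rownames(inst$x))

  big <- max(abs(fit0$d)) + 1
  fitb <- nsc_train(inst$x, inst$y, delta = big)
  expect_true(all(fitb$d_shrunk == 0))
  expect_identical(fitb$surviving_genes, character(0))
  expect_equal(unname(fitb$shrunken_centroids[, 1]),
               unname(fitb$xbar), tolerance = 1e-12)
})

test_that("prediction follows the discriminant hand example and tie rule", {
  # one gene, centroids -1 and +1, s + s0 = 1, equal priors
  fit <- structure(list(
    classes = c("c1", "c2"), xbar = c(g = 0),
    centroids = cbind(c1 = c(g = -1), c2 = c(g = 1)),
    s = c(g = 0.5), s0 = 0.5, m_k = c(c1 = 0.5, c2 = 0.5),
    priors = c(c1 = 0.5, c2 = 0.5), delta = 0,
    d = cbind(c1 = c(g = -1), c2 = c(g = 1)),
    d_shrunk = cbind(c1 = c(g = -1), c2 = c(g = 1)),
    shrunken_centroids = cbind(c1 = c(g = -1), c2 = c(g = 1)),
    surviving_genes = "g"), class = "nsc")
  pred <- predict(fit, c(g = 0.9))
  expect_identical(pred$class, "c2")
  expect_equal(unname(pred$scores[1, ] - (-2 * log(0.5))),
               c(3.61, 0.01), tolerance = 1e-12)
  # exact tie at x = 0 goes to the first declared class
  expect_identical(predict(fit, c(g = 0))$class, "c1")
})

test_that("a sample at a shrunken centroid is assigned to that class", {
  set.seed(41)
  inst <- random_nsc_instance(2)
  fit <- nsc_train(inst$x, inst$y, delta = 0.3,
                   priors = c(A = 0.5, B = 0.5))
  for (k in fit$classes)
    expect_identical(predict(fit, fit$shrunken_centroids[, k])$class, k)
})

test_that("under total shrinkage prediction is by priors alone", {
  set.seed(42)
  inst <- random_nsc_instance(3)
  fit <- nsc_train(inst$x, inst$y, delta = 1e6,
                   priors = c(A = 0.9, B = 0.1))
  preds <- predict(fit, inst$x)$class
  expect_true(all(preds == "A"))
})

test_that("training matches the naive-loop oracle across random instances", {
  for (seed in 1:8) {
    inst <- random_nsc_instance(seed)
    fit0 <- nsc_train(inst$x, inst$y, delta = 0)
    grid <- seq(0, max(abs(fit0$d)), length.out = 8)
    for (delta in grid) {
      fit <- nsc_train(inst$x, inst$y, delta = delta)
      orc <- oracle_nsc(inst$x, inst$y, delta)
      expect_equal(unname(fit$d), unname(orc$d), tolerance = 1e-10)
      expect_equal(unname(fit$d_shrunk), unname(orc$dprime),
                   tolerance = 1e-10)
      bl <- borderline_genes(orc$d, delta)
      expect_identical(setdiff(fit$surviving_genes, bl),
                       setdiff(orc$surviving, bl))
      if (length(bl) == 0)
        for (i in seq_len(ncol(inst$x)))
          expect_identical(predict(fit, inst$x[, i])$class,
                           orc$predict_one(inst$x[, i]))
    }
  }
})

test_that("surviving gene sets shrink monotonically along the grid", {
  inst <- random_nsc_instance(9)
  fit0 <- nsc_train(inst$x, inst$y, delta = 0)
  grid <- seq(0, max(abs(fit0$d)) * 1.01, length.out = 12)
  sets <- lapply(grid, function(d)
    nsc_train(inst$x, inst$y, delta = d)$surviving_genes)
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  expect_identical(sets[[length(sets)]], character(0))
})

test_that("invalid training inputs are rejected", {
  inst <- random_nsc_instance(10)
  expect_error(nsc_train(inst$x, inst$y, delta = -1), "non-negative")
  y1 <- inst$y; y1[y1 == "B"] <- "A"
  expect_error(nsc_train(inst$x, droplevels(y1)), "2 classes")
  ysmall <- factor(c("A", rep("B", length(inst$y) - 1)))
  expect_error(nsc_train(inst$x, ysmall), "fewer than 2 samples")
  expect_error(nsc_train(inst$x, inst$y, priors = c(A = 0.6, B = 0.6)),
               "sum to 1")
  fit <- nsc_train(inst$x, inst$y)
  expect_error(predict(fit, c(zzz = 1)), "g01")
})

test_that("the plus offset variant changes m_k as documented", {
  inst <- random_nsc_instance(11)
  n <- ncol(inst$x)
  nk <- table(inst$y)
  fit <- nsc_train(inst$x, inst$y, offset_variant = "plus")
  expect_equal(unname(fit$m_k),
               unname(sqrt(1 / as.numeric(nk) + 1 / n)))
})

test_that("LOOCV is zero on well-separated classes and refits at the chosen delta", {
  set.seed(43)
  x <- toy_matrix(matrix(rnorm(16 * 20, sd = 0.3), 16, 20))
  y <- factor(rep(c("MUT", "WT"), each = 10), levels = c("MUT", "WT"))
  x[1:6, y == "MUT"] <- x[1:6, y == "MUT"] + 4
  cv <- nsc_loocv(x, y)
  expect_equal(cv$errors[1], 0)
  expect_equal(cv$error_rate, 0)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_identical(cv$final_model$delta, cv$chosen_delta)
  # parsimony: the surviving set is a non-empty subset of the
  # informative genes (the largest zero-error threshold keeps few)
  expect_gte(length(cv$surviving_genes), 1L)
  expect_true(all(cv$surviving_genes %in% rownames(x)[1:6]))
})

test_that("delta ties are broken toward the largest (most parsimonious) delta", {
  set.seed(44)
  x <- toy_matrix(matrix(rnorm(10 * 16, sd = 0.2), 10, 16))
  y <- factor(rep(c("A", "B"), each = 8))
  x[1:3, y == "A"] <- x[1:3, y == "A"] + 5
  cv <- nsc_loocv(x, y)
  zero_err <- cv$delta_grid[cv$errors == min(cv$errors)]
  expect_equal(cv$chosen_delta, max(zero_err))
})

test_that("sensitivity and specificity are the printed quotients", {
  set.seed(45)
  x <- toy_matrix(matrix(rnorm(12 * 20), 12, 20))
  y <- factor(rep(c("MUT", "WT"), 10), levels = c("MUT", "WT"))
  cv <- nsc_loocv(x, y)
  expect_equal(cv$sensitivity,
               cv$sens_counts[["correct"]] / cv$sens_counts[["total"]])
  expect_equal(cv$specificity,
               cv$spec_counts[["correct"]] / cv$spec_counts[["total"]])
  expect_identical(cv$sens_counts[["total"]], 10L)
  expect_identical(cv$positive_class, "MUT")
  out <- capture.output(print(cv))
  expect_match(out[2], "= \\d+/10.*= \\d+/10")
})

test_that("the chosen-threshold surviving set recovers the effect-carrying genes", {
  sig <- ras_signature_genes()
  jac <- numeric(10)
  for (s in 1:10) {
    ch <- generate_cohort(cohort_config(seed = 400L + s))
    bg <- sprintf("BG%04d", 1:18)  # as many null genes as signature genes
    gm <- collapse_by_mean(ch$ff_microarray, c(sig, bg))
    cv <- nsc_loocv(gm$values, ch$labels[colnames(gm$values)])
    jac[s] <- jaccard(cv$surviving_genes, sig)
  }
  expect_gte(mean(jac), 0.5)
})

test_that("folds that would empty a class are rejected", {
  x <- toy_matrix(matrix(rnorm(8 * 5), 8, 5))
  y <- factor(c("A", "A", "A", "B", "B"))
  expect_error(nsc_loocv(x, y), "fewer than 2 training samples")
})

test_that("LOOCV predictions at delta 0 equal the plain standardized centroid rule", {
  inst <- random_nsc_instance(12)
  cv <- nsc_loocv(inst$x, inst$y, delta_grid = 0)
  for (i in seq_len(ncol(inst$x)))
    expect_identical(
      unname(cv$predictions[i, 1]),
      plain_standardized_centroid_predict(inst$x[, -i, drop = FALSE],
                                          inst$y[-i], inst$x[, i]))
})
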