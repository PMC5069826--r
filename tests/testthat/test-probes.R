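test_that("fold-change retention matches the hand-worked 5-sample probes", {
  m <- toy_matrix(rbind(c(0, 0, 0, 0, 1),
                        c(0, 0, 0, 0, 0.5)),
                  features = c("keep", "drop"))
  rep <- filter_probes(expression_matrix(m, "log2"))
  # |1 - 0| = 1 >= log2(1.5) in exactly 1/5 = 20% of samples
  expect_identical(rep$retained_probe_ids, "keep")
  expect_identical(rep$dropped$probe_id, "drop")
  expect_identical(rep$dropped$reason, "fold_change")
})

test_that("missingness threshold is 'at most', over all samples", {
  m <- toy_matrix(rbind(c(0, 10, NA, NA, NA),      # 60% missing
                        c(0, 10, 0, 0, NA),        # 20% missing, big change
                        c(NA, NA, NA, NA, NA)),    # all missing
                  features = c("p60", "p20", "pall"))
  rep <- filter_probes(expression_matrix(m, "log2"))
  expect_identical(rep$retained_probe_ids, "p20")
  expect_setequal(rep$dropped$probe_id, c("p60", "pall"))
  expect_true(all(rep$dropped$reason == "missingness"))
  # exactly 50% missing is retained when fold change passes
  m2 <- toy_matrix(rbind(c(0, 5, NA, NA)), features = "half")
  expect_identical(filter_probes(
    expression_matrix(m2, "log2"))$retained_probe_ids, "half")
})

test_that("report is exhaustive and records lost signature genes", {
  set.seed(5)
  m <- toy_matrix(matrix(rnorm(40, sd = 2), 10, 4))
  m[1, ] <- 0  # flat probe fails fold change
  em <- expression_matrix(m, "log2",
                          feature_to_gene = setNames(
                            rep(c("SIGA", "OTHER"), each = 5),
                            rownames(m)))
  m[2:5, ] <- m[2:5, ] * 0  # all SIGA probes flat
  em$values <- m
  rep <- filter_probes(em, signature = c("SIGA", "SIGB"))
  expect_setequal(c(rep$retained_probe_ids, rep$dropped$probe_id),
                  rownames(m))
  expect_identical(rep$dropped_signature_genes, "SIGA")
})

test_that("near-unit fold change with full missingness tolerance retains everything varying", {
  set.seed(6)
  m <- toy_matrix(matrix(rnorm(50), 10, 5))
  params <- probe_filter_params(fold_change = 1 + 1e-9,
                                max_missing_fraction = 1)
  rep <- filter_probes(expression_matrix(m, "log2"), params)
  expect_identical(rep$retained_probe_ids, rownames(m))
})

test_that("linear-scale mode uses the ratio criterion", {
  m <- toy_matrix(rbind(c(10, 10, 10, 10, 16),
                        c(10, 10, 10, 10, 14)),
                  features = c("keep", "drop"))
  rep <- filter_probes(expression_matrix(m, "log2"),
                       probe_filter_params(values_are_log2 = FALSE))
  expect_identical(rep$retained_probe_ids, "keep")
})

test_that("collapse_by_mean averages probes per gene", {
  m <- toy_matrix(rbind(c(2, 4), c(4, 8), c(1, 1)),
                  features = c("A_p1", "A_p2", "B_p1"))
  em <- expression_matrix(m, "log2",
                          feature_to_gene = c(A_p1 = "A", A_p2 = "A",
                                              B_p1 = "B"))
  out <- collapse_by_mean(em)
  expect_equal(unname(out$values["A", ]), c(3, 6))
  expect_equal(unname(out$values["B", ]), c(1, 1))  # single probe passes through
  expect_error(collapse_by_mean(em, genes = c("A", "Z")), "Z")
})

test_that("18 requested genes yield exactly 18 gene rows", {
  ch <- generate_cohort(small_cohort_config())
  out <- collapse_by_mean(ch$ff_microarray, ras_signature_genes())
  expect_identical(nrow(out$values), 18L)
  expect_identical(rownames(out$values), ras_signature_genes())
})

test_that("max-mean probe selection keeps the argmax row unchanged, ties to smallest id", {
  m <- toy_matrix(rbind(c(5, 5.2), c(7.2, 7.4), c(3, 3), c(3, 3)),
                  features = c("A_p1", "A_p2", "B_p2", "B_p1"))
  em <- expression_matrix(m, "log2",
                          feature_to_gene = c(A_p1 = "A", A_p2 = "A",
                                              B_p2 = "B", B_p1 = "B"))
  sel <- select_max_mean_probe(em, rownames(m))
  expect_identical(unname(sel$gene_to_probe["A"]), "A_p2")  # higher mean
  expect_identical(unname(sel$gene_to_probe["B"]), "B_p1")  # tie -> lexicographic
  expect_identical(unname(sel$matrix$values["A", ]), unname(m["A_p2", ]))
  # subset of input rows, one per gene
  expect_identical(sort(rownames(sel$matrix$values)), c("A", "B"))
})

test_that("genes without retained probes vanish; empty retained set warns", {
  m <- toy_matrix(rbind(c(1, 2), c(3, 4)), features = c("A_p1", "B_p1"))
  em <- expression_matrix(m, "log2",
                          feature_to_gene = c(A_p1 = "A", B_p1 = "B"))
  sel <- select_max_mean_probe(em, "A_p1")
  expect_identical(rownames(sel$matrix$values), "A")
  expect_warning(empty <- select_max_mean_probe(em, character(0)),
                 "empty")
  expect_identical(nrow(empty$matrix$values), 0L)
})

test_that("restrict_signature keeps order, logs drops, errors when empty", {
  sig <- ras_signature_genes()
  reduced <- suppressMessages(
    restrict_signature(sig, setdiff(sig, c("LZTS1", "ZFP106"))))
  expect_length(reduced, 16L)
  expect_identical(reduced, setdiff(sig, c("LZTS1", "ZFP106")))
  expect_message(restrict_signature(sig, "DUSP4"), "17")
  expect_identical(suppressMessages(restrict_signature(sig, "DUSP4")),
                   "DUSP4")
  expect_identical(restrict_signature(sig, sig), sig)
  expect_error(suppressMessages(restrict_signature(sig, "NOPE")),
               "no signature gene")
})

test_that("collapsing then scoring equals scoring the collapsed matrix", {
  set.seed(9)
  ch <- generate_cohort(small_cohort_config())
  sig <- ras_signature_genes()
  collapsed <- collapse_by_mean(ch$ff_microarray, sig)
  s1 <- signature_score(collapsed, sig)$scores
  # manual average of probe-level means
  map <- ch$ff_microarray$feature_to_gene
  manual <- colMeans(do.call(rbind, lapply(sig, function(g)
    colMeans(ch$ff_microarray$values[names(map)[map == g], , drop = FALSE]))))
  expect_equal(unname(s1), unname(manual), tolerance = 1e-12)
})
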