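#' Pipeline configuration
#'
#' Collects every knob the end-to-end workflow needs: the cohort (to
#' simulate, or a directory to load), probe-filter parameters, the PC1
#' outlier threshold, the shrinkage grid size and the datasets to
#' classify.
#'
#' @param mode `"simulate"` (default) generates a cohort from
#'   `cohort`; `"load"` reads one from `input_dir` (a
#'   [write_cohort()] directory).
#' @param cohort A [cohort_config()] (simulate mode).
#' @param input_dir Cohort directory (load mode).
#' @param filter A [probe_filter_params()].
#' @param pc1_threshold PC1 outlier threshold. Default -0.10.
#' @param n_delta Shrinkage-grid size for [nsc_loocv()]. Default 30.
#' @param classify_datasets Datasets to cross-validate; any of
#'   `"ff_microarray"`, `"ffpe_microarray"`, `"ffpe_nanostring"`.
#' @param signature Signature panel; default the 18-gene RAS set.
#' @param seed Seed recorded in the manifest and forwarded to the
#'   cohort config in simulate mode.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            cohort = NULL,
                            input_dir = NULL,
                            filter = probe_filter_params(),
                            pc1_threshold = -0.10,
                            n_delta = 30L,
                            classify_datasets = c("ff_microarray",
                                                  "ffpe_microarray",
                                                  "ffpe_nanostring"),
                            signature = ras_signature_genes(),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("load mode requires an existing 'input_dir'", call. = FALSE)
  } else if (is.null(cohort)) {
    cohort <- cohort_config(seed = seed)
  }
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 filter = filter, pc1_threshold = pc1_threshold,
                 n_delta = as.integer(n_delta),
                 classify_datasets = classify_datasets,
                 signature = signature, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full FF-to-FFPE signature translation workflow
#'
#' Executes, in order: cohort simulation (or loading); platform
#' normalization (housekeeping geometric-mean for NanoString-style
#' counts, per-sample median for targeted counts, log2 + z-score for
#' FPKM; microarray data arrive already on a normalized log2 scale);
#' full-signature scoring of every dataset with probes collapsed by
#' gene means; PCA sample QC on the full FFPE microarray feature
#' matrix with PC1-threshold outlier flagging; probe filtration on the
#' QC-passed FFPE microarray samples followed by max-mean-signal probe
#' selection and signature restriction (the reduced signature);
#' reduced-signature scoring; the four concordance tables
#' ({all samples, QC-passed} x {full, reduced signature}); and a
#' leave-one-out cross-validated shrunken-centroid classifier of
#' mutation status per requested dataset, on all samples with the
#' reduced signature. When `out_dir` is given every stage's table is
#' written as TSV along with a run manifest (seed, parameters,
#' package version); identical config and seed reproduce the files
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param verbose Log stage-level progress and counts via `message()`.
#' @return A list of class `"pipeline_result"` with elements `cohort`,
#'   `normalized` (per-platform gene-level matrices), `scores_full`,
#'   `qc`, `flagged`, `filter_report`, `reduced_signature`,
#'   `gene_to_probe`, `scores_reduced`, `concordance` (named list:
#'   `all_full`, `all_reduced`, `good_full`, `good_reduced`), `cv`
#'   (named list of [nsc_loocv()] reports), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[ffpesig] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sig <- config$signature

  cohort <- stage("input", {
    if (config$mode == "simulate") generate_cohort(config$cohort)
    else read_cohort(config$input_dir)
  })
  say("cohort: %d samples, %d probes on arrays",
      ncol(cohort$latent_log2), length(cohort$probe_to_gene))

  normalized <- stage("normalize", {
    hk <- intersect(housekeeping_genes(),
                    feature_ids(cohort$ffpe_nanostring))
    list(
      ff_microarray = collapse_by_mean(cohort$ff_microarray),
      ffpe_microarray = collapse_by_mean(cohort$ffpe_microarray),
      ffpe_nanostring = housekeeping_normalize(cohort$ffpe_nanostring,
                                               hk)$matrix,
      ffpe_targeted = median_normalize(cohort$ffpe_targeted),
      ffpe_fpkm = suppressWarnings(
        log2_zscore_normalize(cohort$ffpe_fpkm)))
  })
  say("normalized %d platforms", length(normalized))

  labels <- c(ff_microarray = "Affy_FF", ffpe_microarray = "Affy_FFPE",
              ffpe_nanostring = "NanoS_FFPE", ffpe_targeted = "tRNA_FFPE",
              ffpe_fpkm = "RNAacc_FFPE")
  score_all <- function(signature, suffix) {
    out <- list()
    for (p in names(normalized)) {
      avail <- restrict_signature(signature,
                                  feature_ids(normalized[[p]]))
      out[[p]] <- signature_score(normalized[[p]], avail,
                                  dataset_label = paste0(labels[[p]],
                                                         suffix))
    }
    out
  }
  scores_full <- stage("score_full",
                       suppressMessages(score_all(sig, "_full")))

  qc <- stage("qc", pca_sample_scores(cohort$ffpe_microarray,
                                      threshold = config$pc1_threshold))
  flagged <- qc$flagged
  say("qc: %d of %d samples flagged at PC1 < %g", length(flagged),
      length(qc$pc1), config$pc1_threshold)

  good <- setdiff(sample_ids(cohort$ffpe_microarray), flagged)
  filter_report <- stage("filter", filter_probes(
    subset_em(cohort$ffpe_microarray, samples = good),
    config$filter, signature = sig))
  say("filter: %d -> %d probes (%d genes)",
      nrow(cohort$ffpe_microarray$values),
      length(filter_report$retained_probe_ids),
      filter_report$retained_gene_count)

  sel <- stage("probe_selection", select_max_mean_probe(
    cohort$ffpe_microarray, filter_report$retained_probe_ids))
  reduced_signature <- stage("restrict_signature", suppressMessages(
    restrict_signature(sig, feature_ids(sel$matrix))))
  say("reduced signature: %d of %d genes", length(reduced_signature),
      length(sig))

  # reduced-signature gene matrices: microarrays use the selected
  # max-mean probe rows; gene-level platforms just restrict genes
  reduced_mats <- stage("reduce", {
    probes <- sel$gene_to_probe[reduced_signature]
    ff_sel <- cohort$ff_microarray$values[probes, , drop = FALSE]
    ffpe_sel <- cohort$ffpe_microarray$values[probes, , drop = FALSE]
    rownames(ff_sel) <- rownames(ffpe_sel) <- reduced_signature
    list(ff_microarray = expression_matrix(ff_sel, "log2"),
         ffpe_microarray = expression_matrix(ffpe_sel, "log2"),
         ffpe_nanostring = normalized$ffpe_nanostring,
         ffpe_targeted = normalized$ffpe_targeted,
         ffpe_fpkm = normalized$ffpe_fpkm)
  })
  scores_reduced <- stage("score_reduced", suppressMessages({
    out <- list()
    for (p in names(reduced_mats)) {
      avail <- restrict_signature(reduced_signature,
                                  feature_ids(reduced_mats[[p]]))
      out[[p]] <- signature_score(reduced_mats[[p]], avail,
                                  dataset_label = paste0(labels[[p]],
                                                         "_reduced"))
    }
    out
  }))

  concordance <- stage("concordance", list(
    all_full = pairwise_concordance(scores_full),
    all_reduced = pairwise_concordance(scores_reduced),
    good_full = pairwise_concordance(scores_full, exclude = flagged),
    good_reduced = pairwise_concordance(scores_reduced,
                                        exclude = flagged)))
  say("concordance: 4 tables of %d pairs",
      choose(length(scores_full), 2))

  cv <- stage("classify", {
    out <- list()
    for (p in config$classify_datasets) {
      out[[p]] <- nsc_loocv(reduced_mats[[p]]$values[reduced_signature, ,
                                                     drop = FALSE],
                            cohort$labels[sample_ids(reduced_mats[[p]])],
                            n_delta = config$n_delta)
      say("classify %s: error %.0f%%, %d surviving genes", p,
          100 * out[[p]]$error_rate, length(out[[p]]$surviving_genes))
    }
    out
  })

  result <- structure(list(cohort = cohort, normalized = normalized,
                           scores_full = scores_full, qc = qc,
                           flagged = flagged,
                           filter_report = filter_report,
                           reduced_signature = reduced_signature,
                           gene_to_probe = sel$gene_to_probe,
                           scores_reduced = scores_reduced,
                           concordance = concordance, cv = cv,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write every pipeline output table to a directory
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create directory '", out_dir, "'", call. = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  cfg <- result$config
  manifest <- data.frame(
    key = c("package", "version", "seed", "mode", "n_samples",
            "pc1_threshold", "fold_change", "min_fraction",
            "max_missing_fraction", "n_delta", "signature_size",
            "reduced_signature_size", "n_flagged"),
    value = c("ffpesig",
              as.character(utils::packageVersion("ffpesig")),
              cfg$seed, cfg$mode,
              length(result$qc$pc1), cfg$pc1_threshold,
              cfg$filter$fold_change, cfg$filter$min_fraction,
              cfg$filter$max_missing_fraction, cfg$n_delta,
              length(cfg$signature), length(result$reduced_signature),
              length(result$flagged)))
  utils::write.table(manifest, fp("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in names(result$normalized))
    write_expression_matrix(result$normalized[[p]],
                            fp(paste0("normalized_", p, ".tsv")))
  for (p in names(result$scores_full))
    write_sample_scores(result$scores_full[[p]],
                        fp(paste0("scores_full_", p, ".tsv")))
  for (p in names(result$scores_reduced))
    write_sample_scores(result$scores_reduced[[p]],
                        fp(paste0("scores_reduced_", p, ".tsv")))
  write_qc_report(result$qc, fp("qc_report.tsv"))
  write_filter_report(result$filter_report, fp("filter_report.tsv"))
  utils::write.table(
    data.frame(gene = names(result$gene_to_probe),
               probe = unname(result$gene_to_probe)),
    fp("gene_to_probe.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(result$reduced_signature, fp("reduced_signature.txt"))
  for (nm in names(result$concordance))
    write_concordance_table(result$concordance[[nm]],
                            fp(paste0("concordance_", nm, ".tsv")))
  for (p in names(result$cv))
    write_cv_report(result$cv[[p]], fp(paste0("cv_", p, ".tsv")),
                    label = p)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  samples: %d (%d flagged by QC)\n", length(x$qc$pc1),
              length(x$flagged)))
  cat(sprintf("  signature: %d genes full, %d reduced\n",
              length(x$config$signature), length(x$reduced_signature)))
  cat(sprintf("  concordance tables: %s\n",
              paste(names(x$concordance), collapse = ", ")))
  for (p in names(x$cv))
    cat(sprintf("  cv %s: error %.0f%%, sens %.3f, spec %.3f\n", p,
                100 * x$cv[[p]]$error_rate, x$cv[[p]]$sensitivity,
                x$cv[[p]]$specificity))
  invisible(x)
}
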