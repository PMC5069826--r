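#' Probe filtration parameters
#'
#' A probe is retained if (a) its expression shows at least a
#' `fold_change`-fold change in either direction of its median level in
#' at least `min_fraction` of the (non-missing) samples, and (b) at
#' most `max_missing_fraction` of its values are missing.
#'
#' @param fold_change Minimum fold change relative to the probe median,
#'   in either direction (> 1). Default 1.5.
#' @param min_fraction Minimum fraction of samples meeting the fold
#'   change, in (0, 1]. Default 0.20.
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   values, in [0, 1]. Default 0.50.
#' @param values_are_log2 If `TRUE` (default) the fold-change test is
#'   `|x - median| >= log2(fold_change)`; otherwise the linear-scale
#'   ratio test `x/median >= fold_change` or `<= 1/fold_change`.
#' @return A list of class `"probe_filter_params"`.
#' @export
probe_filter_params <- function(fold_change = 1.5, min_fraction = 0.20,
                                max_missing_fraction = 0.50,
                                values_are_log2 = TRUE) {
  if (fold_change <= 1) stop("'fold_change' must exceed 1", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must be in (0, 1]", call. = FALSE)
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("'max_missing_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(fold_change = fold_change, min_fraction = min_fraction,
                 max_missing_fraction = max_missing_fraction,
                 values_are_log2 = isTRUE(values_are_log2)),
            class = "probe_filter_params")
}

#' Filter probes by fold change and missingness
#'
#' Applies the criteria in [probe_filter_params()] to every probe.
#' Medians and sample fractions are computed over non-missing entries
#' only; a probe with all entries missing is dropped for missingness,
#' never an error. The report is exhaustive: every input probe appears
#' either in `retained_probe_ids` or in `dropped` with its reason.
#'
#' @param matrix An [expression_matrix()] of probe-level values.
#' @param params A [probe_filter_params()].
#' @param signature Optional gene list; when given, signature genes
#'   whose probes are all dropped are recorded in
#'   `dropped_signature_genes`.
#' @return A list of class `"filter_report"` with
#'   `retained_probe_ids`, `dropped` (data frame `probe_id`, `reason`
#'   in `{"missingness", "fold_change"}`), `retained_gene_count`,
#'   `dropped_signature_genes`, and `params`.
#' @export
filter_probes <- function(matrix, params = probe_filter_params(),
                          signature = NULL) {
  v <- matrix$values
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("empty expression matrix", call. = FALSE)
  miss_frac <- rowMeans(is.na(v))
  thr <- log2(params$fold_change)
  pass_fc <- vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    x <- x[!is.na(x)]
    if (!length(x)) return(FALSE)
    med <- stats::median(x)
    hit <- if (params$values_are_log2) {
      abs(x - med) >= thr
    } else {
      if (med == 0) x != 0 else
        (x / med >= params$fold_change) | (x / med <= 1 / params$fold_change)
    }
    mean(hit) >= params$min_fraction
  }, logical(1))

  fail_missing <- miss_frac > params$max_missing_fraction
  retained <- rownames(v)[!fail_missing & pass_fc]
  dropped_ids <- setdiff(rownames(v), retained)
  reason <- ifelse(fail_missing[dropped_ids], "missingness", "fold_change")
  dropped <- data.frame(probe_id = dropped_ids, reason = unname(reason),
                        stringsAsFactors = FALSE)
  genes_kept <- unique(matrix$feature_to_gene[retained])
  dropped_sig <- if (is.null(signature)) character(0) else
    setdiff(intersect(signature, matrix$feature_to_gene), genes_kept)
  structure(list(retained_probe_ids = retained, dropped = dropped,
                 retained_gene_count = length(genes_kept),
                 dropped_signature_genes = dropped_sig,
                 params = params),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d probes retained (%d genes), %d dropped\n",
              length(x$retained_probe_ids), x$retained_gene_count,
              nrow(x$dropped)))
  if (nrow(x$dropped))
    print(table(x$dropped$reason))
  if (length(x$dropped_signature_genes))
    cat("signature genes with no surviving probe:",
        paste(x$dropped_signature_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Write a filter report to TSV
#'
#' One row per input probe with columns `probe_id`, `status`
#' (`retained`/`dropped`) and `reason`.
#'
#' @param report A [filter_probes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- rbind(
    data.frame(probe_id = report$retained_probe_ids, status = "retained",
               reason = "", stringsAsFactors = FALSE),
    data.frame(probe_id = report$dropped$probe_id, status = "dropped",
               reason = report$dropped$reason, stringsAsFactors = FALSE))
  df <- df[order(df$probe_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probes to genes by averaging
#'
#' For each requested gene, the gene-level value per sample is the
#' arithmetic mean over that gene's probes (non-missing entries).
#' Output features are gene symbols.
#'
#' @param matrix A probe-level [expression_matrix()].
#' @param genes Genes to collapse; defaults to every gene in the map.
#'   A requested gene with no probes is an error.
#' @return A gene-level [expression_matrix()] (identity gene map).
#' @export
collapse_by_mean <- function(matrix, genes = NULL) {
  map <- matrix$feature_to_gene
  if (is.null(genes)) genes <- unique(unname(map))
  absent <- setdiff(genes, map)
  if (length(absent))
    stop("gene(s) with no probes in matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  v <- matrix$values
  out <- vapply(genes, function(g) {
    rows <- names(map)[map == g]
    colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(v)))
  out <- t(out)
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(genes, colnames(v))
  expression_matrix(out, scale = matrix$scale)
}

#' Reduce probes to one per gene by maximum mean signal
#'
#' Among the retained probes of each gene, keeps exactly the probe with
#' the highest across-sample mean signal; ties are broken toward the
#' lexicographically smallest probe id. Rows are copied unchanged (no
#' value mutation); output features are gene symbols. Genes with no
#' retained probe are absent from the output.
#'
#' @param matrix A probe-level [expression_matrix()].
#' @param retained Probe ids to consider (e.g.
#'   `filter_probes(...)$retained_probe_ids`); must be a subset of the
#'   matrix features.
#' @return A list with `matrix` (gene-level [expression_matrix()]) and
#'   `gene_to_probe` (named character: selected probe per gene).
#' @export
select_max_mean_probe <- function(matrix, retained) {
  bad <- setdiff(retained, feature_ids(matrix))
  if (length(bad))
    stop("retained probe(s) not in matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!length(retained)) {
    warning("empty retained probe set; returning empty matrix",
            call. = FALSE)
    empty <- matrix$values[0, , drop = FALSE]
    return(list(matrix = expression_matrix(empty, scale = matrix$scale),
                gene_to_probe = character(0)))
  }
  v <- matrix$values[retained, , drop = FALSE]
  means <- rowMeans(v, na.rm = TRUE)
  map <- matrix$feature_to_gene[retained]
  # order by gene, then decreasing mean, then probe id; first wins
  ord <- order(map, -means, retained)
  keep <- ord[!duplicated(map[ord])]
  probes <- retained[keep]
  genes <- unname(map[keep])
  out <- v[probes, , drop = FALSE]
  rownames(out) <- genes
  list(matrix = expression_matrix(out, scale = matrix$scale),
       gene_to_probe = stats::setNames(probes, genes))
}

#' Restrict a signature to the available genes
#'
#' Ordered intersection of a signature panel with an available gene
#' set, preserving panel order. Dropped symbols are reported via
#' `message()`; an empty intersection is an error.
#'
#' @param signature Character vector of signature gene symbols.
#' @param available Character vector of available gene symbols.
#' @return The restricted signature (character vector).
#' @export
restrict_signature <- function(signature, available) {
  if (!length(signature)) stop("empty signature", call. = FALSE)
  kept <- signature[signature %in% available]
  dropped <- setdiff(signature, kept)
  if (length(dropped))
    message("restrict_signature: dropping ", length(dropped), " gene(s): ",
            paste(dropped, collapse = ", "))
  if (!length(kept))
    stop("no signature gene is available", call. = FALSE)
  kept
}
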