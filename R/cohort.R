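#' Configuration for a synthetic matched FF/FFPE cohort
#'
#' Describes the study design the generator emulates: matched
#' fresh-frozen (FF) and formalin-fixed paraffin-embedded (FFPE)
#' tumour pairs measured on several platforms, a two-class mutation
#' structure (MUT vs WT) that shifts signature-gene expression, and a
#' per-sample RNA-quality factor with a planted subset of degraded
#' ("bad") samples.
#'
#' @param n_samples Cohort size (number of matched pairs). Default 54.
#' @param n_background_genes Non-signature, non-housekeeping genes on
#'   the genome-wide platforms. Default 1000.
#' @param signature_genes Signature panel; default the 18-gene RAS set.
#' @param housekeeping_genes Reference panel; default the 11-gene set.
#'   Must be disjoint from `signature_genes`.
#' @param probes_per_gene_range Integer interval `c(lo, hi)`: each gene
#'   carries between `lo` and `hi` microarray probes. Default `c(1, 4)`.
#' @param class_fraction_mut Fraction of samples labelled MUT.
#'   Default 0.5 (a balanced 27/27 design at n = 54).
#' @param signature_effect Log2-scale shift added to signature genes in
#'   MUT samples. Default 1.0.
#' @param n_bad_samples Number of planted low-RNA-quality samples.
#'   Default 15. Must be `< n_samples`.
#' @param quality_good,quality_bad Intervals in (0, 1] from which
#'   good/bad per-sample quality factors are drawn uniformly. Defaults
#'   `c(0.85, 1)` and `c(0.2, 0.5)`.
#' @param noise_sd_biological Log2-scale sd of gene-by-sample
#'   biological noise in the latent matrix. Default 0.7.
#' @param noise_sd_technical Log2-scale sd of per-platform measurement
#'   noise (inflated on degraded samples). Default 0.25.
#' @param seed Integer RNG seed; the same seed reproduces the cohort
#'   bit-for-bit.
#'
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 54L,
                          n_background_genes = 1000L,
                          signature_genes = ras_signature_genes(),
                          housekeeping_genes = ffpesig::housekeeping_genes(),
                          probes_per_gene_range = c(1L, 4L),
                          class_fraction_mut = 0.5,
                          signature_effect = 1.0,
                          n_bad_samples = 15L,
                          quality_good = c(0.85, 1.0),
                          quality_bad = c(0.2, 0.5),
                          noise_sd_biological = 0.7,
                          noise_sd_technical = 0.25,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_background_genes = as.integer(n_background_genes),
              signature_genes = as.character(signature_genes),
              housekeeping_genes = as.character(housekeeping_genes),
              probes_per_gene_range = as.integer(probes_per_gene_range),
              class_fraction_mut = class_fraction_mut,
              signature_effect = signature_effect,
              n_bad_samples = as.integer(n_bad_samples),
              quality_good = as.numeric(quality_good),
              quality_bad = as.numeric(quality_bad),
              noise_sd_biological = noise_sd_biological,
              noise_sd_technical = noise_sd_technical,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stop_if <- function(bad, ...) if (bad) stop(..., call. = FALSE)
  stop_if(cfg$n_samples < 1L, "n_samples must be positive")
  stop_if(cfg$n_background_genes < 1L, "n_background_genes must be positive")
  stop_if(length(cfg$signature_genes) < 1L, "signature_genes must be non-empty")
  overlap <- intersect(cfg$signature_genes, cfg$housekeeping_genes)
  stop_if(length(overlap) > 0L,
          "signature and housekeeping gene lists overlap: ",
          paste(overlap, collapse = ", "))
  stop_if(anyDuplicated(cfg$signature_genes) ||
            anyDuplicated(cfg$housekeeping_genes),
          "gene lists must not contain duplicates")
  r <- cfg$probes_per_gene_range
  stop_if(length(r) != 2L || r[1] < 1L || r[2] < r[1],
          "probes_per_gene_range must be an ordered positive interval")
  stop_if(cfg$class_fraction_mut < 0 || cfg$class_fraction_mut > 1,
          "class_fraction_mut must be in [0, 1]")
  stop_if(cfg$n_bad_samples < 0L || cfg$n_bad_samples >= cfg$n_samples,
          "n_bad_samples must satisfy 0 <= n_bad_samples < n_samples")
  for (nm in c("quality_good", "quality_bad")) {
    q <- cfg[[nm]]
    stop_if(length(q) != 2L || q[1] > q[2] || q[1] <= 0 || q[2] > 1,
            nm, " must be an ordered interval within (0, 1]")
  }
  stop_if(cfg$noise_sd_biological < 0 || cfg$noise_sd_technical < 0,
          "noise sds must be non-negative")
  invisible(cfg)
}

# Fixed structural constants of the degradation model; see the methods
# vignette for rationale. `floor` is the log2 background toward which
# degraded measurements are pulled.
.cohort_const <- list(
  floor = 1.0,          # log2 background signal
  mu_mean = 7, mu_sd = 1.5,          # baseline gene means, log2
  mu_hk_mean = 9.5, mu_hk_sd = 0.3,  # housekeeping: high, stable
  sample_offset_sd = 0.2,            # per-sample latent size effect
  probe_offset_sd = 0.5,             # per-probe affinity offset, log2
  size_factor_log2_sd = 0.2)         # per-sample platform size factors

#' Generate a synthetic matched FF/FFPE multi-platform cohort
#'
#' Draws a latent gene-by-sample log2 expression matrix
#' `x[g, s] = mu_g + a_s + beta * 1(g in signature & label_s == MUT) + eps`,
#' with `eps ~ N(0, noise_sd_biological^2)`, then produces platform
#' measurements from it:
#' \itemize{
#'   \item `ff_microarray`, `ffpe_microarray`: probe-level log2 values,
#'     each probe `p` of gene `g` reporting `x[g, s] + offset_p` plus
#'     technical noise. FFPE values are degraded toward a background
#'     floor: `floor + q_s * (value - floor)` with per-sample quality
#'     `q_s` in (0, 1], and heteroscedastic noise with variance
#'     `noise_sd_technical^2 * (2 - q_s)`.
#'   \item `ffpe_nanostring`, `ffpe_targeted`: gene-level non-negative
#'     integer counts on the signature + housekeeping panel, obtained
#'     by exponentiating the degraded log2 values and scaling by a
#'     per-sample size factor before rounding.
#'   \item `ffpe_fpkm`: gene-level FPKM-scale values (exponentiated,
#'     not rounded) for all genes.
#' }
#' Housekeeping genes receive no class effect. A planted subset of
#' `n_bad_samples` samples draws its quality factor from the low
#' `quality_bad` interval; all other samples (and the FF platform,
#' where `q = 1`) are essentially undegraded.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"synthetic_cohort"` with elements
#'   `latent_log2`, `ff_microarray`, `ffpe_microarray`,
#'   `ffpe_nanostring`, `ffpe_targeted`, `ffpe_fpkm` (the five platform
#'   [expression_matrix()] objects share one sample ordering),
#'   `quality` (named numeric), `planted_bad` (character),
#'   `labels` (named factor, levels MUT/WT), `probe_to_gene` (named
#'   character) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  k <- .cohort_const

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_samples
  # barcode-style zero-padded sample ids
  samples <- sprintf("S%03d", seq_len(n))
  sig <- config$signature_genes
  hk <- config$housekeeping_genes
  background <- sprintf("BG%04d", seq_len(config$n_background_genes))
  genes <- c(sig, hk, background)

  mu <- c(stats::rnorm(length(sig), k$mu_mean, k$mu_sd),
          stats::rnorm(length(hk), k$mu_hk_mean, k$mu_hk_sd),
          stats::rnorm(length(background), k$mu_mean, k$mu_sd))
  names(mu) <- genes

  a <- stats::rnorm(n, 0, k$sample_offset_sd)

  n_mut <- round(n * config$class_fraction_mut)
  labels <- factor(sample(c(rep("MUT", n_mut), rep("WT", n - n_mut))),
                   levels = c("MUT", "WT"))
  names(labels) <- samples

  effect <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  effect[sig, labels == "MUT"] <- config$signature_effect

  latent <- outer(mu, rep(1, n)) + outer(rep(1, length(genes)), a) + effect +
    matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd_biological),
           length(genes), n)
  dimnames(latent) <- list(genes, samples)

  # per-sample RNA quality; FF is measured at q = 1
  bad <- sort(sample(samples, config$n_bad_samples))
  quality <- stats::runif(n, config$quality_good[1], config$quality_good[2])
  names(quality) <- samples
  quality[bad] <- stats::runif(config$n_bad_samples,
                               config$quality_bad[1], config$quality_bad[2])

  # microarray probe registry (shared by FF and FFPE arrays)
  r <- config$probes_per_gene_range
  n_probes <- if (r[1] == r[2]) rep(r[1], length(genes)) else
    sample(seq(r[1], r[2]), length(genes), replace = TRUE)
  probe_gene <- rep(genes, n_probes)
  probes <- sprintf("%s_p%d", probe_gene, unlist(lapply(n_probes, seq_len)))
  probe_to_gene <- stats::setNames(probe_gene, probes)
  probe_offset <- stats::setNames(
    stats::rnorm(length(probes), 0, k$probe_offset_sd), probes)

  tech <- config$noise_sd_technical
  probe_latent <- latent[probe_gene, , drop = FALSE] + probe_offset
  rownames(probe_latent) <- probes

  tech_noise <- function(nr, q) {
    # per-sample sd inflated on degraded samples: var = tech^2 * (2 - q)
    matrix(stats::rnorm(nr * n), nr, n) *
      outer(rep(1, nr), tech * sqrt(2 - q))
  }
  degrade <- function(m, q) {
    k$floor + sweep(m - k$floor, 2, q, `*`)
  }

  ff_vals <- probe_latent +
    matrix(stats::rnorm(length(probe_latent), 0, tech),
           nrow(probe_latent), n)
  ffpe_vals <- degrade(probe_latent, quality) +
    tech_noise(nrow(probe_latent), quality)
  dimnames(ff_vals) <- dimnames(ffpe_vals) <- list(probes, samples)

  ff_microarray <- expression_matrix(ff_vals, "log2", probe_to_gene)
  ffpe_microarray <- expression_matrix(ffpe_vals, "log2", probe_to_gene)

  panel <- c(sig, hk)
  gene_platform <- function(gene_set, count = TRUE) {
    m <- degrade(latent[gene_set, , drop = FALSE], quality) +
      tech_noise(length(gene_set), quality)
    sf <- 2^stats::rnorm(n, 0, k$size_factor_log2_sd)
    v <- sweep(2^m, 2, sf, `*`)
    if (count) v <- pmax(round(v), 0)
    dimnames(v) <- list(gene_set, samples)
    v
  }
  ffpe_nanostring <- expression_matrix(gene_platform(panel), "count")
  ffpe_targeted <- expression_matrix(gene_platform(panel), "count")
  ffpe_fpkm <- expression_matrix(gene_platform(genes, count = FALSE), "fpkm")

  structure(list(latent_log2 = latent,
                 ff_microarray = ff_microarray,
                 ffpe_microarray = ffpe_microarray,
                 ffpe_nanostring = ffpe_nanostring,
                 ffpe_targeted = ffpe_targeted,
                 ffpe_fpkm = ffpe_fpkm,
                 quality = quality,
                 planted_bad = bad,
                 labels = labels,
                 probe_to_gene = probe_to_gene,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d planted bad), %d genes, %d probes\n",
    length(x$quality), length(x$planted_bad), nrow(x$latent_log2),
    length(x$probe_to_gene)))
  cat("  platforms: ff_microarray, ffpe_microarray, ffpe_nanostring,",
      "ffpe_targeted, ffpe_fpkm\n")
  cat(sprintf("  classes: MUT %d / WT %d\n",
              sum(x$labels == "MUT"), sum(x$labels == "WT")))
  invisible(x)
}

.cohort_platforms <- c("ff_microarray", "ffpe_microarray",
                       "ffpe_nanostring", "ffpe_targeted", "ffpe_fpkm")

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes one TSV matrix per platform (features as rows, sample ids as
#' header), the probe-to-gene map, the latent matrix, per-sample class
#' labels and quality factors. Everything round-trips through
#' [read_cohort()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory '", dir, "'", call. = FALSE)
  for (p in .cohort_platforms)
    write_expression_matrix(cohort[[p]], file.path(dir, paste0(p, ".tsv")))
  write_expression_matrix(
    expression_matrix(cohort$latent_log2, "log2"),
    file.path(dir, "latent_log2.tsv"))
  wt <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(data.frame(probe_id = names(cohort$probe_to_gene),
                gene_symbol = unname(cohort$probe_to_gene)),
     file.path(dir, "probe_map.tsv"))
  wt(data.frame(sample_id = names(cohort$labels),
                class = as.character(cohort$labels)),
     file.path(dir, "labels.tsv"))
  wt(data.frame(sample_id = names(cohort$quality),
                quality = unname(cohort$quality),
                planted_bad = names(cohort$quality) %in% cohort$planted_bad),
     file.path(dir, "quality.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSV files.
#' @return A list of class `"synthetic_cohort"` (without the generating
#'   `config`).
#' @export
read_cohort <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file '", p, "'", call. = FALSE)
    p
  }
  pm <- utils::read.delim(need("probe_map.tsv"), stringsAsFactors = FALSE)
  probe_to_gene <- stats::setNames(pm$gene_symbol, pm$probe_id)
  scales <- c(ff_microarray = "log2", ffpe_microarray = "log2",
              ffpe_nanostring = "count", ffpe_targeted = "count",
              ffpe_fpkm = "fpkm")
  out <- list()
  for (p in .cohort_platforms) {
    map <- if (grepl("microarray", p)) probe_to_gene else NULL
    out[[p]] <- read_expression_matrix(need(paste0(p, ".tsv")),
                                       scale = scales[[p]],
                                       feature_to_gene = map)
  }
  out$latent_log2 <- read_expression_matrix(need("latent_log2.tsv"),
                                            scale = "log2")$values
  lab <- utils::read.delim(need("labels.tsv"), stringsAsFactors = FALSE)
  out$labels <- stats::setNames(factor(lab$class, levels = c("MUT", "WT")),
                                lab$sample_id)
  qual <- utils::read.delim(need("quality.tsv"), stringsAsFactors = FALSE)
  out$quality <- stats::setNames(qual$quality, qual$sample_id)
  out$planted_bad <- qual$sample_id[qual$planted_bad]
  out$probe_to_gene <- probe_to_gene
  structure(out, class = "synthetic_cohort")
}
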