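# Shared fixture builders; everything is generated in code at test time.

# A small matrix with gene rownames / sample colnames.
toy_matrix <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, fast cohort configuration for structural tests.
small_cohort_config <- function(...) {
  args <- list(n_samples = 12L, n_background_genes = 40L,
               n_bad_samples = 3L, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}
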