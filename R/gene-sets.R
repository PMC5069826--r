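#' The 18-gene RAS pathway activation signature
#'
#' The composite RAS/MEK/ERK pathway activation panel used throughout
#' the package: the per-sample mean expression of these genes is the
#' sample's signature score. Note the token `SLCO4A` is kept exactly as
#' published with the panel; the current HGNC symbol for that gene is
#' `SLCO4A1`.
#'
#' @return Character vector of 18 gene symbols, in panel order.
#' @export
ras_signature_genes <- function() {
  read_gene_list(system.file("extdata", "ras_signature_18.txt",
                             package = "ffpesig", mustWork = TRUE))
}

#' The 11-gene housekeeping (reference) panel
#'
#' Reference genes assumed stably expressed across samples, used by
#' [housekeeping_normalize()] to derive per-sample normalization
#' factors for count-scale (NanoString-style) data.
#'
#' @return Character vector of 11 gene symbols.
#' @export
housekeeping_genes <- function() {
  read_gene_list(system.file("extdata", "housekeeping_11.txt",
                             package = "ffpesig", mustWork = TRUE))
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and leading/trailing whitespace are ignored.
#'
#' @param path Path to a plain-text file with one gene symbol per line.
#' @return Character vector of symbols, file order preserved.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path))
    stop("no such file: '", path, "'", call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
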