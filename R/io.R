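# Readers for the tabular formats the pipeline consumes. Matrices come back
# as base matrices with dimnames; record tables as tibbles.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a gene x sample count matrix from TSV
#'
#' First column is the gene id; remaining columns are samples.
#'
#' @param path Path to the TSV.
#' @return Integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_quiet(path)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read a probe x sample beta matrix from TSV
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with probe rownames.
#' @export
read_beta_matrix <- function(path) {
  read_count_matrix(path)
}

#' Read a sample sheet (sample_id, cancer_type, condition)
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_quiet(path)
  need <- setdiff(c("sample_id", "cancer_type", "condition"), names(df))
  if (length(need) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (any(!df$condition %in% c("normal", "tumor"))) {
    abort("sample sheet condition must be 'normal' or 'tumor'")
  }
  df
}

#' Read a TSS table (tss_id, gene_id, chrom, position, strand)
#'
#' Positions are 1-based in the file and converted downstream.
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_tss_table <- function(path) {
  df <- read_tsv_quiet(path)
  need <- setdiff(c("tss_id", "gene_id", "chrom", "position", "strand"),
                  names(df))
  if (length(need) > 0) {
    abort(paste0("TSS table lacks column(s): ", paste(need, collapse = ", ")))
  }
  df
}

#' Read a probe manifest (probe_id, chrom, position)
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_probe_manifest <- function(path) {
  df <- read_tsv_quiet(path)
  need <- setdiff(c("probe_id", "chrom", "position"), names(df))
  if (length(need) > 0) {
    abort(paste0("probe manifest lacks column(s): ",
                 paste(need, collapse = ", ")))
  }
  df
}

#' Read an enhancer-to-gene link table
#'
#' @param path Path to the TSV (peak_id, chrom, start, end, gene_id,
#'   correlation).
#' @return Tibble.
#' @export
read_link_table <- function(path) {
  df <- read_tsv_quiet(path)
  need <- setdiff(c("peak_id", "chrom", "start", "end", "gene_id"), names(df))
  if (length(need) > 0) {
    abort(paste0("link table lacks column(s): ", paste(need, collapse = ", ")))
  }
  df
}

#' Read gene lengths (gene_id, length)
#'
#' @param path Path to the TSV.
#' @return Named numeric vector.
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv_quiet(path)
  stats::setNames(df$length, df$gene_id)
}
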