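# Cross-cancer statistics on the class calls: plastic genes, cancer-type-
# restricted genes, PCA distance ratios, signature scoring and stratified
# tests.

#' Plastic genes across cancer types
#'
#' A gene is plastic iff it is upregulated in one cancer type and promoter-
#' hypermethylated in another, within the same PRC2 class (`UP_PRC2` in A and
#' `HYPER_PRC2` in B, or `UP_PRC2NEG` / `HYPER_PRC2NEG`). The per-type
#' percentage divides the plastic genes among that type's upregulated genes
#' by the number of upregulated genes in that type.
#'
#' @param class_calls Tibble with `gene_id`, `cancer_type`, `label` covering
#'   at least two cancer types.
#' @return A list: `summary` (tibble per cancer type and PRC2 class:
#'   `n_upregulated`, `n_plastic`, `pct_plastic`) and `plastic_genes` (named
#'   list of global plastic gene ids per PRC2 class).
#' @export
plastic_genes <- function(class_calls) {
  if (dplyr::n_distinct(class_calls$cancer_type) < 2) {
    abort("plastic genes need class calls from at least 2 cancer types")
  }
  one_class <- function(up_label, hyper_label) {
    up <- class_calls |> filter(.data$label == up_label)
    hy <- class_calls |> filter(.data$label == hyper_label)
    plastic <- sort(unique(
      dplyr::inner_join(select(up, "gene_id", up_type = "cancer_type"),
                        select(hy, "gene_id", hy_type = "cancer_type"),
                        by = "gene_id", relationship = "many-to-many") |>
        filter(.data$up_type != .data$hy_type) |>
        pull(.data$gene_id)
    ))
    summ <- up |>
      group_by(cancer_type = .data$cancer_type) |>
      summarise(n_upregulated = dplyr::n_distinct(.data$gene_id),
                n_plastic = dplyr::n_distinct(
                  .data$gene_id[.data$gene_id %in% plastic]),
                .groups = "drop") |>
      mutate(pct_plastic = .data$n_plastic / .data$n_upregulated)
    list(summary = summ, plastic = plastic)
  }
  pos <- one_class("UP_PRC2", "HYPER_PRC2")
  neg <- one_class("UP_PRC2NEG", "HYPER_PRC2NEG")
  summary <- bind_rows(
    mutate(pos$summary, prc2_class = "PRC2_POS", .before = 1),
    mutate(neg$summary, prc2_class = "PRC2_NEG", .before = 1)
  )
  list(summary = summary,
       plastic_genes = list(PRC2_POS = pos$plastic, PRC2_NEG = neg$plastic))
}

#' Cancer-type-restricted genes
#'
#' Within a class gene set, genes whose mean tumor expression in the target
#' cancer type is at least `fc_cutoff`-fold that of all other tumors
#' (pseudo-floor `eps`), optionally also requiring a one-vs-rest NB test with
#' BH-adjusted p < 0.05.
#'
#' @param expr Expression matrix used for the fold change (FPKM; genes x
#'   tumor samples).
#' @param tumor_sample_types Named character vector mapping each tumor column
#'   to its cancer type.
#' @param class_gene_set Candidate gene ids (e.g. the UP_PRC2 genes of the
#'   target type).
#' @param target_type Cancer type of interest.
#' @param fc_cutoff Fold-change threshold (default 2, `>=`).
#' @param counts Optional count matrix over the same tumors; when supplied,
#'   the one-vs-rest significance requirement is applied.
#' @param eps Pseudo-floor added to both means (default 0.01).
#' @return Tibble `gene_id`, `fold_change`, `padj` (NA without `counts`),
#'   `restricted`.
#' @export
cancer_restricted_genes <- function(expr, tumor_sample_types, class_gene_set,
                                    target_type, fc_cutoff = 2, counts = NULL,
                                    eps = 0.01) {
  if (length(class_gene_set) == 0) {
    return(tibble(gene_id = character(), fold_change = numeric(),
                  padj = numeric(), restricted = logical()))
  }
  sample_ids <- names(tumor_sample_types)
  in_t <- sample_ids[tumor_sample_types == target_type]
  out_t <- sample_ids[tumor_sample_types != target_type]
  if (length(in_t) < 2 || length(out_t) < 2) {
    abort("need >= 2 tumors in the target type and in the rest")
  }
  genes <- intersect(class_gene_set, rownames(expr))
  m_in <- rowMeans(expr[genes, in_t, drop = FALSE])
  m_out <- rowMeans(expr[genes, out_t, drop = FALSE])
  fc <- (m_in + eps) / (m_out + eps)
  padj <- rep(NA_real_, length(genes))
  if (!is.null(counts)) {
    de <- nb_two_group_test(counts[genes, , drop = FALSE], out_t, in_t)
    padj <- de$padj[match(genes, de$gene_id)]
  }
  ok <- fc >= fc_cutoff & (is.null(counts) | (!is.na(padj) & padj < 0.05))
  tibble(gene_id = genes, fold_change = unname(fc), padj = padj,
         restricted = unname(ok))
}

#' Inter/intra PCA distance ratio
#'
#' PCA on log2(FPKM + 1) restricted to a gene set, genes centered across
#' samples; Euclidean distances in the first `n_pcs` components. Returns the
#' mean distance between samples of different cancer types divided by the
#' mean distance between samples of the same type (`Inf` when the
#' intra-distance is exactly 0).
#'
#' @param expr FPKM matrix (genes x samples).
#' @param sample_types Named character vector mapping samples to cancer
#'   types (>= 2 types, >= 2 samples each).
#' @param gene_set Gene ids to use (at least `n_pcs` present in `expr`).
#' @param n_pcs Number of principal components (default 2).
#' @return A single non-negative number (possibly `Inf`).
#' @export
pca_distance_ratio <- function(expr, sample_types, gene_set, n_pcs = 2) {
  samples <- names(sample_types)
  tt <- table(sample_types)
  if (length(tt) < 2 || any(tt < 2)) {
    abort("need >= 2 cancer types with >= 2 samples each")
  }
  genes <- intersect(gene_set, rownames(expr))
  if (length(genes) < n_pcs) abort("gene set smaller than n_pcs")
  x <- log2(expr[genes, samples, drop = FALSE] + 1)
  x <- x - rowMeans(x)
  if (all(abs(x) < 1e-12)) abort("degenerate (zero-variance) expression input")
  pc <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  d <- as.matrix(stats::dist(pc$x[, seq_len(k), drop = FALSE]))
  same <- outer(sample_types, sample_types, "==")
  ut <- upper.tri(d)
  intra <- mean(d[ut & same])
  inter <- mean(d[ut & !same])
  if (intra == 0) return(Inf)
  inter / intra
}

#' Per-sample signature score
#'
#' Mean of log2(FPKM + 1) over the listed genes, per sample. Genes absent
#' from the matrix are dropped with a warning.
#'
#' @param expr FPKM matrix (genes x samples).
#' @param gene_list Character vector of signature genes.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, gene_list) {
  genes <- intersect(gene_list, rownames(expr))
  if (length(genes) == 0) abort("no signature gene present in the matrix")
  if (length(genes) < length(gene_list)) {
    warn(sprintf("%d signature gene(s) absent from the matrix dropped",
                 length(gene_list) - length(genes)))
  }
  colMeans(log2(expr[genes, , drop = FALSE] + 1))
}

#' One-sided Welch test between top and bottom strata
#'
#' Samples are stratified into the top and bottom `quantile` fraction of a
#' stratifying score; a second outcome score is compared between the strata
#' by a one-sided Welch t-test (alternative: top > bottom).
#'
#' @param data Data frame with one row per sample.
#' @param strat,outcome Column names (strings) of the stratifying and outcome
#'   scores.
#' @param quantile Fraction in each stratum (default 0.2; use 0.2 for
#'   quintiles).
#' @param alternative Passed to [stats::t.test()] (default `"greater"`).
#' @return One-row tibble: `statistic`, `p`, `n_top`, `n_bottom`,
#'   `mean_top`, `mean_bottom`.
#' @export
stratified_group_test <- function(data, strat, outcome, quantile = 0.2,
                                  alternative = "greater") {
  s <- data[[strat]]
  y <- data[[outcome]]
  n <- length(s)
  k <- max(2L, floor(quantile * n))
  if (n < 2 * k || k < 2) abort("strata smaller than 2 samples")
  ord <- order(s)
  bottom <- y[ord[seq_len(k)]]
  top <- y[ord[seq(n - k + 1, n)]]
  if (stats::sd(top) == 0 && stats::sd(bottom) == 0) {
    p <- if (mean(top) == mean(bottom)) 0.5 else
      as.numeric(mean(top) < mean(bottom))
    return(tibble(statistic = 0, p = p, n_top = k, n_bottom = k,
                  mean_top = mean(top), mean_bottom = mean(bottom)))
  }
  tt <- stats::t.test(top, bottom, alternative = alternative)
  tibble(statistic = unname(tt$statistic), p = tt$p.value, n_top = k,
         n_bottom = k, mean_top = mean(top), mean_bottom = mean(bottom))
}

#' Fold change of TF targets between TF-high and TF-low tumors
#'
#' Tumors are split into the upper and lower `quantile` of the TF's own
#' expression; each target's fold change is the ratio of mean expression
#' (pseudo-floor `eps`) between the two groups, categorized as `up`
#' (FC >= `fc_cutoff`), `down` (FC <= 1/`fc_cutoff`) or `unchanged`.
#'
#' @param expr FPKM matrix (genes x tumor samples).
#' @param tf_gene Gene id of the transcription factor (must be in `expr`).
#' @param target_genes Target gene ids.
#' @param quantile Stratum fraction (default 0.2, i.e. quintiles).
#' @param fc_cutoff Linear fold-change cutoff (default 1.5).
#' @param eps Pseudo-floor (default 0.01).
#' @return Tibble `gene_id`, `fold_change`, `category`.
#' @export
tf_stratified_target_fc <- function(expr, tf_gene, target_genes,
                                    quantile = 0.2, fc_cutoff = 1.5,
                                    eps = 0.01) {
  if (!tf_gene %in% rownames(expr)) {
    abort(sprintf("TF gene %s absent from the expression matrix", tf_gene))
  }
  tfx <- expr[tf_gene, ]
  n <- length(tfx)
  k <- floor(quantile * n)
  if (k < 2) abort("fewer than 2 samples per quantile stratum")
  ord <- order(tfx)
  low <- colnames(expr)[ord[seq_len(k)]]
  high <- colnames(expr)[ord[seq(n - k + 1, n)]]
  genes <- intersect(target_genes, rownames(expr))
  fc <- (rowMeans(expr[genes, high, drop = FALSE]) + eps) /
    (rowMeans(expr[genes, low, drop = FALSE]) + eps)
  tibble(
    gene_id = genes, fold_change = unname(fc),
    category = dplyr::case_when(fc >= fc_cutoff ~ "up",
                                fc <= 1 / fc_cutoff ~ "down",
                                TRUE ~ "unchanged")
  )
}

#' Bundled CD8+ T-cell cytotoxicity signatures
#'
#' Two published immune signatures used for stratified scoring of tumors:
#' signature A (chemokine/antigen-presentation panel) and signature B
#' (GZMA/PRF1 cytolytic score). Shipped as a GMT file under `extdata`.
#'
#' @return Named list of gene-id vectors.
#' @export
cd8_signatures <- function() {
  read_gmt(system.file("extdata", "cd8_signatures.gmt", package = "cgiplast"))
}
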