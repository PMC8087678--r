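# ggplot2 convenience layers; values in the result tables are the contract,
# the plots are views on them.

#' Class counts per cancer type
#'
#' @param result A `cgip_result` from [run_pipeline()], or its `class_calls`
#'   tibble.
#' @return A ggplot object.
#' @export
plot_class_counts <- function(result) {
  calls <- if (inherits(result, "cgip_result")) result$class_calls else result
  calls |>
    filter(.data$label != "NONE") |>
    dplyr::count(.data$cancer_type, .data$label) |>
    ggplot(aes(x = .data$cancer_type, y = .data$n, fill = .data$label)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "genes", fill = "class") +
    theme_minimal()
}

#' TSS-centered signal profile curves
#'
#' @param x A `cgip_profile` from [tss_signal_profile()].
#' @param ... Unused.
#' @return A ggplot object (per-class mean curves when class labels were
#'   supplied, otherwise the overall mean curve).
#' @exportS3Method ggplot2::autoplot
autoplot.cgip_profile <- function(x, ...) {
  df <- if (!is.null(x$class_mean)) x$class_mean else {
    tibble(class = "all", bin_mid = x$bin_mid, value = colMeans(x$matrix))
  }
  ggplot(df, aes(x = .data$bin_mid, y = .data$value, colour = .data$class)) +
    geom_line() +
    labs(x = "distance from TSS (bp)", y = "mean signal", colour = NULL) +
    theme_minimal()
}

#' Enrichment dot plot
#'
#' @param enrichment Output of [binomial_z_enrichment()] or
#'   [hypergeom_region_enrichment()].
#' @return A ggplot object of -log10 p per set/TF.
#' @export
plot_enrichment <- function(enrichment) {
  id_col <- if ("set_id" %in% names(enrichment)) "set_id" else "tf"
  df <- mutate(enrichment, neglogp = -log10(pmax(.data$p, 1e-300)))
  pl <- ggplot(df, aes(x = .data$neglogp,
                       y = stats::reorder(.data[[id_col]], .data$neglogp)))
  if ("direction" %in% names(df)) {
    pl <- pl + geom_point(aes(colour = .data$direction))
  } else {
    pl <- pl + geom_point(aes(colour = .data$enriched))
  }
  pl + labs(x = expression(-log[10] ~ p), y = NULL) + theme_minimal()
}

#' PCA of tumor samples on a class gene set
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param sample_types Named character vector mapping samples to types.
#' @param gene_set Gene ids used for the projection.
#' @return A ggplot object of the first two components.
#' @export
plot_class_pca <- function(fpkm, sample_types, gene_set) {
  genes <- intersect(gene_set, rownames(fpkm))
  x <- log2(fpkm[genes, names(sample_types), drop = FALSE] + 1)
  x <- x - rowMeans(x)
  pc <- stats::prcomp(t(x), center = FALSE)
  tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
         cancer_type = unname(sample_types)) |>
    ggplot(aes(x = .data$PC1, y = .data$PC2, colour = .data$cancer_type)) +
    geom_point(alpha = 0.8) +
    labs(colour = NULL) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
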