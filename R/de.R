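# Expression preprocessing and the self-contained negative-binomial
# two-group test (median-of-ratios normalization, moment dispersion, Wald
# statistic) with BH correction.

#' FPKM from raw counts
#'
#' `FPKM_gs = count_gs * 1e9 / (length_g * total_counts_s)` with per-sample
#' totals taken over all genes in the matrix.
#'
#' @param counts Integer count matrix, genes x samples, gene rownames.
#' @param gene_lengths Named numeric vector of transcript lengths (bp).
#' @return FPKM matrix with the same dimnames.
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  if (is.null(rownames(counts))) abort("`counts` needs gene rownames")
  gl <- gene_lengths[rownames(counts)]
  if (any(is.na(gl))) abort("gene_lengths missing for some count rows")
  if (any(gl <= 0)) abort("gene lengths must be > 0")
  tot <- colSums(counts)
  if (any(tot == 0)) abort("sample(s) with zero library size")
  sweep(counts * 1e9 / gl, 2, tot, "/")
}

#' Expressed-gene filter
#'
#' A gene passes iff strictly more than `detect_frac` of nonmalignant *and*
#' of tumor samples have count > 0, and strictly more than `fpkm_frac` of
#' tumor samples have FPKM > `fpkm_cutoff`.
#'
#' @param counts,fpkm Matrices (genes x samples) sharing dimnames.
#' @param normal_ids,tumor_ids Sample id vectors.
#' @param detect_frac Detection fraction (strict `>`), default 0.8.
#' @param fpkm_cutoff FPKM threshold (strict `>`), default 1.
#' @param fpkm_frac Tumor fraction over threshold (strict `>`), default 0.5.
#' @return Named logical vector per gene.
#' @export
expression_filter <- function(counts, fpkm, normal_ids, tumor_ids,
                              detect_frac = 0.8, fpkm_cutoff = 1,
                              fpkm_frac = 0.5) {
  if (length(normal_ids) == 0 || length(tumor_ids) == 0) {
    abort("both sample groups must be non-empty")
  }
  det_n <- rowMeans(counts[, normal_ids, drop = FALSE] > 0)
  det_t <- rowMeans(counts[, tumor_ids, drop = FALSE] > 0)
  fp_t <- rowMeans(fpkm[, tumor_ids, drop = FALSE] > fpkm_cutoff)
  out <- det_n > detect_frac & det_t > detect_frac & fp_t > fpkm_frac
  stats::setNames(out, rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1 (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Negative-binomial two-group Wald test
#'
#' A self-contained NB test for tumor-vs-nonmalignant comparisons:
#' median-of-ratios size factors (genes with any zero are excluded from the
#' geometric-mean reference), per-gene dispersion by method of moments on the
#' normalized counts (floored at 1e-8), log2 fold change from normalized
#' group means (pseudo-count 0.5 only when a group mean is zero, keeping the
#' estimate invariant to library rescaling), delta-method standard error, and
#' a Wald
#' statistic referred to a t distribution with `n_a + n_b - 2` degrees of
#' freedom (two-sided). BH adjustment is applied over filter-passing genes
#' only.
#'
#' @param counts Count matrix, genes x samples, with dimnames.
#' @param group_a_ids,group_b_ids Sample ids of the two groups (A = reference,
#'   e.g. nonmalignant; B = tumor; `log2fc` is B vs A). At least 2 samples
#'   each.
#' @param passed_filter Optional named logical vector from
#'   [expression_filter()]; `NULL` means all genes pass.
#' @return A `cgip_de` tibble: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `stat`, `p`, `padj`, `passed_filter`.
#' @export
nb_two_group_test <- function(counts, group_a_ids, group_b_ids,
                              passed_filter = NULL) {
  if (length(group_a_ids) < 2 || length(group_b_ids) < 2) {
    abort("each group needs at least 2 samples")
  }
  ids <- c(group_a_ids, group_b_ids)
  missing_s <- setdiff(ids, colnames(counts))
  if (length(missing_s) > 0) {
    abort(sprintf("sample(s) absent from counts: %s",
                  paste(utils::head(missing_s, 3), collapse = ", ")))
  }
  cts <- counts[, ids, drop = FALSE]
  if (any(colSums(cts) == 0)) abort("sample(s) with all-zero library")

  logg <- rowMeans(log(cts))
  ref_ok <- is.finite(logg)
  if (!any(ref_ok)) abort("no gene has positive counts in every sample")
  sf <- apply(cts, 2, function(x) {
    exp(stats::median((log(x) - logg)[ref_ok & x > 0]))
  })
  q <- sweep(cts, 2, sf, "/")
  a <- seq_along(group_a_ids)
  b <- length(group_a_ids) + seq_along(group_b_ids)
  na <- length(a); nb <- length(b)
  ma <- rowMeans(q[, a, drop = FALSE])
  mb <- rowMeans(q[, b, drop = FALSE])
  mu <- rowMeans(q)
  v <- (rowSums((q[, a, drop = FALSE] - ma)^2) +
          rowSums((q[, b, drop = FALSE] - mb)^2)) / (na + nb - 2)
  alpha <- pmax((v - mu) / mu^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8

  # zero-guard pseudo-count: only genes with an all-zero group mean get it,
  # so the fold change is exactly invariant to library rescaling elsewhere
  pc <- ifelse(ma == 0 | mb == 0, 0.5, 0)
  lfc <- log2((mb + pc) / (ma + pc))
  inv_sf_a <- sum(1 / sf[a]); inv_sf_b <- sum(1 / sf[b])
  var_ma <- (ma * inv_sf_a + alpha * ma^2 * na) / na^2
  var_mb <- (mb * inv_sf_b + alpha * mb^2 * nb) / nb^2
  se <- sqrt(var_ma / (ma + 0.5)^2 + var_mb / (mb + 0.5)^2) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)

  pf <- if (is.null(passed_filter)) {
    stats::setNames(rep(TRUE, nrow(cts)), rownames(cts))
  } else passed_filter[rownames(cts)]
  padj <- rep(NA_real_, nrow(cts))
  padj[pf] <- bh_adjust(p[pf])

  out <- tibble(
    gene_id = rownames(cts), base_mean = mu, log2fc = lfc, se = se,
    stat = stat, p = p, padj = padj, passed_filter = unname(pf)
  )
  class(out) <- c("cgip_de", class(out))
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  out
}

#' @exportS3Method generics::tidy
tidy.cgip_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cgip_de")
  out
}

#' @exportS3Method generics::glance
glance.cgip_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(x$passed_filter),
    n_signif = sum(x$padj < 0.05, na.rm = TRUE),
    n_up = sum(x$padj < 0.05 & x$log2fc > 1, na.rm = TRUE),
    n_a = attr(x, "n_a"),
    n_b = attr(x, "n_b")
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
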