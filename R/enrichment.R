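# Reciprocal foreground/background enrichment statistics: binomial z-test
# over gene sets, one-sided hypergeometric motif enrichment with a TF
# expression gate, Fisher peak-overlap tests and enhancer-link summaries.

#' Binomial z-test gene-set enrichment, run in both directions
#'
#' For each set, `k/n` is the foreground hit rate and the background rate is
#' continuity-guarded as `p0 = (k_bg + 0.5) / (n_bg + 1)`; the statistic is
#' `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)` with a one-sided upper-tail
#' normal p. The test is repeated with foreground and background swapped.
#'
#' @param fg_genes,bg_genes Disjoint, non-empty gene-id vectors.
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param p_cutoff Raw one-sided p threshold flagged in `enriched`
#'   (default 0.05, matching unadjusted-p filtering; `padj` is also
#'   reported).
#' @return Tibble with one row per set and direction: `set_id`, `direction`,
#'   `k_fg`, `n_fg`, `k_bg`, `n_bg`, `p0`, `z`, `p`, `padj`, `enriched`.
#' @export
binomial_z_enrichment <- function(fg_genes, bg_genes, gene_sets,
                                  p_cutoff = 0.05) {
  fg_genes <- unique(fg_genes); bg_genes <- unique(bg_genes)
  if (length(fg_genes) == 0 || length(bg_genes) == 0) {
    abort("foreground and background must be non-empty")
  }
  if (length(intersect(fg_genes, bg_genes)) > 0) {
    abort("foreground and background must be disjoint")
  }
  empty <- lengths(gene_sets) == 0
  if (any(empty)) {
    inform(sprintf("%d empty gene set(s) skipped", sum(empty)))
    gene_sets <- gene_sets[!empty]
  }
  one_dir <- function(fg, bg, direction) {
    purrr::imap_dfr(gene_sets, function(set, id) {
      k <- length(intersect(fg, set)); n <- length(fg)
      kb <- length(intersect(bg, set)); nb <- length(bg)
      p0 <- (kb + 0.5) / (nb + 1)
      z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
      tibble(set_id = id, direction = direction, k_fg = k, n_fg = n,
             k_bg = kb, n_bg = nb, p0 = p0, z = z,
             p = stats::pnorm(z, lower.tail = FALSE))
    })
  }
  out <- bind_rows(one_dir(fg_genes, bg_genes, "fg_vs_bg"),
                   one_dir(bg_genes, fg_genes, "bg_vs_fg"))
  out |>
    group_by(.data$direction) |>
    mutate(padj = bh_adjust(.data$p)) |>
    ungroup() |>
    mutate(enriched = .data$p < p_cutoff & .data$z > 0)
}

#' One-sided hypergeometric motif enrichment over regions
#'
#' A region "has" a TF's motif iff at least one occurrence overlaps it. With
#' `N` total regions, `K` regions carrying the motif, `n` foreground regions
#' and `k` foreground regions with the motif, the p-value is
#' `P(X >= k)` under Hypergeometric(N, K, n). TFs are reported as enriched
#' when `p < p_cutoff` and the TF's median tumor FPKM exceeds `fpkm_cutoff`.
#'
#' @param fg_regions,bg_regions Disjoint interval tibbles.
#' @param motif_occurrences Named list (by TF gene id) of occurrence interval
#'   tibbles.
#' @param tf_fpkm Named numeric vector: median tumor FPKM per TF. TFs absent
#'   from it are excluded with a warning.
#' @param fpkm_cutoff Expression gate (default 10, strict `>`).
#' @param p_cutoff Raw p threshold (default 0.01, strict `<`).
#' @return Tibble per TF: `tf`, `k_fg`, `n_fg`, `k_bg`, `n_bg`, `p`, `padj`,
#'   `median_fpkm`, `expressed`, `enriched`.
#' @export
hypergeom_region_enrichment <- function(fg_regions, bg_regions,
                                        motif_occurrences, tf_fpkm,
                                        fpkm_cutoff = 10, p_cutoff = 0.01) {
  fg_regions <- as_intervals(fg_regions, "fg_regions")
  bg_regions <- as_intervals(bg_regions, "bg_regions")
  known <- names(motif_occurrences) %in% names(tf_fpkm)
  if (!all(known)) {
    warn(sprintf("TF(s) absent from the expression matrix excluded: %s",
                 paste(names(motif_occurrences)[!known], collapse = ", ")))
    motif_occurrences <- motif_occurrences[known]
  }
  out <- purrr::imap_dfr(motif_occurrences, function(occ, tf) {
    k <- sum(overlap_any(fg_regions, occ))
    kb <- sum(overlap_any(bg_regions, occ))
    n <- nrow(fg_regions); nb <- nrow(bg_regions)
    N <- n + nb; K <- k + kb
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(tf = tf, k_fg = k, n_fg = n, k_bg = kb, n_bg = nb, p = p,
           median_fpkm = unname(tf_fpkm[tf]))
  })
  if (nrow(out) == 0) return(out)
  out |>
    mutate(padj = bh_adjust(.data$p),
           expressed = .data$median_fpkm > fpkm_cutoff,
           enriched = .data$p < p_cutoff & .data$expressed) |>
    select("tf", "k_fg", "n_fg", "k_bg", "n_bg", "p", "padj",
           "median_fpkm", "expressed", "enriched")
}

#' Two-sided Fisher exact test on a 2x2 feature table
#'
#' Exact two-sided p (sum of tables with probability at most that of the
#' observed table, via [stats::fisher.test()]) and the sample odds ratio,
#' with a Haldane correction of 0.5 added to every cell when any cell is
#' zero.
#'
#' @param table2x2 A 2x2 matrix of non-negative counts, e.g. rows = gene
#'   class, columns = feature present/absent.
#' @return One-row tibble: `odds_ratio`, `p`.
#' @export
fisher_overlap_test <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2, 2))) abort("need a 2x2 table")
  if (any(m < 0)) abort("cell counts must be non-negative")
  p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  mm <- if (any(m == 0)) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  tibble(odds_ratio = or, p = p)
}

#' Mean enhancer links per gene, by gene class
#'
#' Counts distinct linked peaks per gene; genes of the class without any
#' link count as 0.
#'
#' @param link_table Tibble with at least `peak_id` and `gene_id`.
#' @param gene_sets_by_class Named list of gene-id vectors.
#' @return Tibble `class`, `n_genes`, `mean_links`.
#' @export
enhancers_per_gene <- function(link_table, gene_sets_by_class) {
  counts <- link_table |>
    distinct(.data$peak_id, .data$gene_id) |>
    dplyr::count(.data$gene_id, name = "n_links")
  purrr::imap_dfr(gene_sets_by_class, function(genes, cls) {
    genes <- unique(genes)
    nl <- counts$n_links[match(genes, counts$gene_id)]
    nl[is.na(nl)] <- 0L
    tibble(class = cls, n_genes = length(genes),
           mean_links = if (length(genes) > 0) mean(nl) else NA_real_)
  })
}

#' Distinct enhancer regions linked to a gene list
#'
#' @param link_table Tibble with `peak_id`, `chrom`, `start`, `end`,
#'   `gene_id`.
#' @param genes Gene ids of interest.
#' @return Interval tibble of distinct linked enhancers (`peak_id`, `chrom`,
#'   `start`, `end`).
#' @export
linked_regions_for_genes <- function(link_table, genes) {
  link_table |>
    filter(.data$gene_id %in% genes) |>
    distinct(.data$peak_id, .data$chrom, .data$start, .data$end) |>
    arrange(.data$chrom, .data$start)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
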