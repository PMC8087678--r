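# Per-cancer-type class calling: hypermethylated promoters, upregulated
# genes, and assembly of the disjoint gene classes.

CLASS_LABELS <- c("HYPER_PRC2", "UP_PRC2", "UP_PRC2NEG", "HYPER_PRC2NEG",
                  "NONE")

#' Call hypermethylated promoters
#'
#' A promoter is called hypermethylated iff strictly more than `low_frac` of
#' nonmalignant samples have beta < `low` *and* strictly more than
#' `high_frac` of tumor samples have beta > `high`. Missing beta values are
#' excluded from both numerator and denominator; a promoter with all-missing
#' nonmalignant values gets `NA`.
#'
#' @param pbeta Promoter beta matrix from [promoter_beta()].
#' @param normal_ids,tumor_ids Sample ids.
#' @param low,low_frac Normal-side threshold (beta < 0.2 in > 90%).
#' @param high,high_frac Tumor-side threshold (beta > 0.3 in > 15%).
#' @return Named logical vector per promoter (NA when undefined).
#' @export
call_hypermethylated_promoters <- function(pbeta, normal_ids, tumor_ids,
                                           low = 0.2, low_frac = 0.9,
                                           high = 0.3, high_frac = 0.15) {
  if (length(normal_ids) == 0 || length(tumor_ids) == 0) {
    abort("both sample groups must be non-empty")
  }
  bn <- pbeta[, normal_ids, drop = FALSE]
  bt <- pbeta[, tumor_ids, drop = FALSE]
  nn <- rowSums(!is.na(bn))
  nt <- rowSums(!is.na(bt))
  frac_low <- rowSums(bn < low, na.rm = TRUE) / nn
  frac_high <- rowSums(bt > high, na.rm = TRUE) / nt
  out <- frac_low > low_frac & frac_high > high_frac
  out[nn == 0 | nt == 0] <- NA
  stats::setNames(out, rownames(pbeta))
}

#' Call upregulated genes from a DE table
#'
#' Upregulated iff the gene passed the expression filter, adjusted p is
#' strictly below `padj_cutoff` and log2 fold change strictly above
#' `lfc_cutoff`.
#'
#' @param de A `cgip_de` tibble from [nb_two_group_test()] (or any table with
#'   `gene_id`, `log2fc`, `padj`, `passed_filter`).
#' @param padj_cutoff,lfc_cutoff Strict thresholds (defaults 0.05 and 1).
#' @return Named logical vector per gene.
#' @export
call_upregulated_genes <- function(de, padj_cutoff = 0.05, lfc_cutoff = 1) {
  up <- de$passed_filter & !is.na(de$padj) & de$padj < padj_cutoff &
    de$log2fc > lfc_cutoff
  stats::setNames(up, de$gene_id)
}

#' Assemble the gene classes for one cancer type
#'
#' Combines PRC2 status, hypermethylation flags and differential expression
#' into one label per gene:
#' * `UP_PRC2` - upregulated gene with at least one `PRC2_POS` CGI promoter
#'   that passed the normal-expression gate;
#' * `UP_PRC2NEG` - upregulated gene whose CGI promoters are all `PRC2_NEG`;
#' * `HYPER_PRC2` - gene with at least one hypermethylated `PRC2_POS`
#'   promoter and no significant upregulation (`log2fc < 1` or adjusted
#'   `p > 0.05`);
#' * `HYPER_PRC2NEG` - the same rule on all-`PRC2_NEG` genes;
#' * `NONE` otherwise. The no-upregulation clause makes HYPER and UP labels
#'   mutually exclusive by construction.
#'
#' @param promoters Output of [classify_prc2()].
#' @param hyper_flags Named logical vector from
#'   [call_hypermethylated_promoters()].
#' @param de `cgip_de` table for this cancer type.
#' @param gated_genes Character vector from [normal_expression_gate()] (PRC2+
#'   genes retained by the normal FPKM gate).
#' @param cancer_type Cancer-type label recorded in the output.
#' @param padj_cutoff,lfc_cutoff Upregulation thresholds.
#' @return Tibble: `gene_id`, `cancer_type`, `label`, `n_promoters`,
#'   `n_hyper_promoters`, `log2fc`, `padj`.
#' @export
assemble_gene_classes <- function(promoters, hyper_flags, de, gated_genes,
                                  cancer_type, padj_cutoff = 0.05,
                                  lfc_cutoff = 1) {
  gmap <- map_genes(promoters)$by_gene |>
    left_join(select(promoters, "promoter_id", "prc2_status"),
              by = "promoter_id") |>
    mutate(hyper = unname(hyper_flags[.data$promoter_id]))

  per_gene <- gmap |>
    group_by(.data$gene_id) |>
    summarise(
      n_promoters = n(),
      n_hyper_promoters = sum(.data$hyper %in% TRUE),
      has_pos = any(.data$prc2_status == "PRC2_POS"),
      all_neg = all(.data$prc2_status == "PRC2_NEG"),
      hyper_pos = any(.data$prc2_status == "PRC2_POS" & .data$hyper %in% TRUE),
      hyper_any = any(.data$hyper %in% TRUE),
      .groups = "drop"
    )

  de_genes <- de$gene_id
  orphan <- setdiff(de_genes, per_gene$gene_id)
  if (length(orphan) > 0) {
    warn(sprintf("%d gene(s) in the DE table have no curated promoter; NONE",
                 length(orphan)))
  }
  up <- call_upregulated_genes(de, padj_cutoff, lfc_cutoff)

  per_gene |>
    left_join(select(de, "gene_id", "log2fc", "padj"), by = "gene_id") |>
    mutate(
      is_up = .data$gene_id %in% names(up)[up],
      # "no significant upregulation": log2fc < 1 or adjusted p > 0.05;
      # genes never tested (no DE row / filtered out) carry no evidence of
      # upregulation and satisfy the clause
      no_up = is.na(.data$padj) | is.na(.data$log2fc) |
        .data$log2fc < lfc_cutoff | .data$padj > padj_cutoff,
      label = dplyr::case_when(
        is_up & has_pos & gene_id %in% gated_genes ~ "UP_PRC2",
        is_up & all_neg ~ "UP_PRC2NEG",
        no_up & hyper_pos ~ "HYPER_PRC2",
        no_up & all_neg & hyper_any ~ "HYPER_PRC2NEG",
        TRUE ~ "NONE"
      ),
      cancer_type = cancer_type
    ) |>
    select("gene_id", "cancer_type", "label", "n_promoters",
           "n_hyper_promoters", "log2fc", "padj")
}
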