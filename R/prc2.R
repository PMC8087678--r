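# PRC2 occupancy annotation from chromatin-state segments and EZH2/SUZ12
# peaks, plus the normal-tissue expression gate.

#' Assign PRC2 status to CGI promoters
#'
#' A promoter is `PRC2_POS` iff it overlaps at least one chromatin-state
#' segment whose state number is in `h3k27me3_states` (bivalent/poised TSS,
#' flanking bivalent, repressed Polycomb by default) *and* at least one EZH2
#' or SUZ12 peak. It is `PRC2_NEG` iff it overlaps neither such a segment nor
#' any subunit peak (no evidence of PRC2 occupancy at all); anything in
#' between is `AMBIGUOUS`.
#'
#' @param promoters Output of [curate_promoters()].
#' @param segments Chromatin-state intervals; the state label (e.g.
#'   `"10_TssBiv"`) must be in the `name` column and start with the state
#'   number.
#' @param ezh2_peaks,suz12_peaks Peak interval tibbles (either may be empty).
#' @param h3k27me3_states Integer state numbers counted as H3K27me3-positive.
#' @return `promoters` with a `prc2_status` column added.
#' @export
classify_prc2 <- function(promoters, segments, ezh2_peaks, suz12_peaks,
                          h3k27me3_states = c(10, 11, 13)) {
  segments <- as_intervals(segments, "segments")
  if (nrow(segments) > 0) {
    state_num <- suppressWarnings(as.integer(sub("_.*$", "", segments$name)))
    bad <- which(is.na(state_num))
    if (length(bad) > 0) {
      abort(sprintf("unparseable chromatin-state label '%s'",
                    segments$name[bad[1]]))
    }
    biv <- segments[state_num %in% h3k27me3_states, , drop = FALSE]
  } else {
    biv <- segments
  }
  peaks <- bind_rows(as_intervals(ezh2_peaks, "ezh2_peaks"),
                     as_intervals(suz12_peaks, "suz12_peaks"))
  has_biv <- overlap_any(promoters, biv)
  has_peak <- if (nrow(peaks) > 0) overlap_any(promoters, peaks) else
    rep(FALSE, nrow(promoters))
  promoters$prc2_status <- dplyr::case_when(
    has_biv & has_peak ~ "PRC2_POS",
    !has_biv & !has_peak ~ "PRC2_NEG",
    TRUE ~ "AMBIGUOUS"
  )
  promoters
}

#' Gene-level PRC2 class
#'
#' A gene is `PRC2_POS` if at least one of its CGI promoters is `PRC2_POS`;
#' `PRC2_NEG` only if *all* its promoters are `PRC2_NEG`; otherwise `MIXED`
#' (ambiguous-only or conflicting evidence), which belongs to neither
#' analysis class.
#'
#' @param promoters Output of [classify_prc2()].
#' @return Tibble `gene_id`, `gene_prc2`.
#' @export
gene_prc2_class <- function(promoters) {
  if (!"prc2_status" %in% names(promoters)) {
    abort("run classify_prc2() first (no `prc2_status` column)")
  }
  map_genes(promoters)$by_gene |>
    left_join(select(promoters, "promoter_id", "prc2_status"),
              by = "promoter_id") |>
    group_by(.data$gene_id) |>
    summarise(gene_prc2 = dplyr::case_when(
      any(.data$prc2_status == "PRC2_POS") ~ "PRC2_POS",
      all(.data$prc2_status == "PRC2_NEG") ~ "PRC2_NEG",
      TRUE ~ "MIXED"
    ), .groups = "drop")
}

#' Normal-tissue expression gate for PRC2+ genes
#'
#' Keeps genes whose median FPKM across the nonmalignant samples is strictly
#' below `cutoff` (default 4), the level that separates PRC2-occupied from
#' active promoters in normal tissue.
#'
#' @param genes Character vector of candidate gene ids.
#' @param fpkm FPKM matrix (genes x samples, gene rownames).
#' @param normal_ids Nonmalignant sample ids (columns of `fpkm`).
#' @param cutoff FPKM threshold (strict `<`).
#' @return Character vector of retained gene ids.
#' @export
normal_expression_gate <- function(genes, fpkm, normal_ids, cutoff = 4) {
  if (length(normal_ids) == 0) abort("no nonmalignant samples for the gate")
  missing_s <- setdiff(normal_ids, colnames(fpkm))
  if (length(missing_s) > 0) {
    abort(sprintf("normal sample(s) absent from fpkm matrix: %s",
                  paste(utils::head(missing_s, 3), collapse = ", ")))
  }
  genes_in <- intersect(genes, rownames(fpkm))
  if (length(genes_in) == 0) return(character(0))
  med <- apply(fpkm[genes_in, normal_ids, drop = FALSE], 1, stats::median)
  genes_in[med < cutoff]
}
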