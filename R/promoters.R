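# CGI-promoter curation: window TSSs, map probes, drop probeless windows,
# merge windows sharing an identical probe set, exclude chrY/chrM, keep CGI
# overlaps, and average probe beta values per promoter.

#' Curate CGI promoters from TSSs, probes and CGI annotation
#'
#' Each TSS is windowed with [promoter_window()]; methylation probes whose
#' CpG coordinate lies inside a window are assigned to it; windows without
#' probes are dropped; windows carrying an *identical* probe set are merged
#' (coordinate union, TSS/gene ids concatenated); promoters on excluded
#' chromosomes are removed; and only promoters overlapping a CGI by at least
#' 1 bp are retained.
#'
#' @param tss_table Tibble with columns `tss_id`, `gene_id`, `chrom`,
#'   `position` (1-based TSS position), `strand`.
#' @param probe_manifest Tibble with columns `probe_id`, `chrom`, `position`
#'   (1-based CpG coordinate).
#' @param cgi_bed CGI intervals (tibble, 0-based half-open).
#' @param excluded_chroms Chromosomes removed from the output.
#' @param upstream,downstream Promoter window extent (bp).
#' @return Tibble of promoters: `promoter_id`, `chrom`, `start`, `end`,
#'   `strand`, and list-columns `tss_ids`, `gene_ids`, `probe_ids`, plus
#'   `is_cgi` (always `TRUE` in the output).
#' @export
curate_promoters <- function(tss_table, probe_manifest, cgi_bed,
                             excluded_chroms = c("chrY", "chrM"),
                             upstream = 250, downstream = 500) {
  tss_table <- as_tibble(tss_table)
  need <- setdiff(c("tss_id", "gene_id", "chrom", "position", "strand"),
                  names(tss_table))
  if (length(need) > 0) {
    abort(paste0("`tss_table` lacks column(s): ", paste(need, collapse = ", ")))
  }
  probe_manifest <- as_tibble(probe_manifest)
  need <- setdiff(c("probe_id", "chrom", "position"), names(probe_manifest))
  if (length(need) > 0) {
    abort(paste0("`probe_manifest` lacks column(s): ",
                 paste(need, collapse = ", ")))
  }

  unknown <- !probe_manifest$chrom %in% unique(tss_table$chrom)
  if (any(unknown)) {
    warn(sprintf("%d probe(s) on chromosomes absent from the TSS table ignored",
                 sum(unknown)))
    probe_manifest <- probe_manifest[!unknown, , drop = FALSE]
  }

  win <- promoter_window(
    tibble(chrom = tss_table$chrom, position = tss_table$position - 1L,
           strand = tss_table$strand,
           tss_id = tss_table$tss_id, gene_id = tss_table$gene_id),
    upstream = upstream, downstream = downstream
  )

  # assign probes by their single CpG coordinate (0-based base)
  probes0 <- tibble(chrom = probe_manifest$chrom,
                    start = probe_manifest$position - 1L,
                    end = probe_manifest$position,
                    probe_id = probe_manifest$probe_id)
  hits <- GenomicRanges::findOverlaps(as_granges0(win), as_granges0(probes0))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  probe_sets <- split(probes0$probe_id[si], qi)
  widx <- as.integer(names(probe_sets))
  if (length(widx) == 0) {
    return(tibble(promoter_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  tss_ids = list(), gene_ids = list(), probe_ids = list(),
                  is_cgi = logical()))
  }

  per_window <- tibble(
    chrom = win$chrom[widx], start = win$start[widx], end = win$end[widx],
    strand = win$strand[widx], tss_id = win$tss_id[widx],
    gene_id = win$gene_id[widx],
    probe_ids = lapply(probe_sets, function(p) sort(unique(p)))
  )
  per_window$probe_key <- vapply(per_window$probe_ids, paste, character(1),
                                 collapse = "|")

  merged <- per_window |>
    group_by(.data$probe_key) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start), end = max(.data$end),
      strand = if (dplyr::n_distinct(.data$strand) == 1) .data$strand[1] else ".",
      tss_ids = list(sort(unique(.data$tss_id))),
      gene_ids = list(sort(unique(.data$gene_id))),
      probe_ids = .data$probe_ids[1],
      .groups = "drop"
    ) |>
    filter(!.data$chrom %in% excluded_chroms) |>
    arrange(.data$chrom, .data$start)

  if (nrow(merged) > 0) {
    merged$is_cgi <- overlap_any(merged, as_intervals(cgi_bed, "cgi_bed"))
    merged <- filter(merged, .data$is_cgi)
  } else {
    merged$is_cgi <- logical(0)
  }
  merged |>
    mutate(promoter_id = sprintf("prom_%05d", row_number())) |>
    select("promoter_id", "chrom", "start", "end", "strand",
           "tss_ids", "gene_ids", "probe_ids", "is_cgi")
}

#' Per-promoter mean methylation
#'
#' For every promoter and sample, the arithmetic mean of the promoter's probe
#' beta values present in that sample (missing probes are dropped from the
#' mean; an all-missing entry stays missing).
#'
#' @param promoters Output of [curate_promoters()].
#' @param probe_beta Numeric matrix of beta values, probes x samples, with
#'   probe ids as rownames.
#' @return Numeric matrix, promoters x samples, rownames = `promoter_id`.
#' @export
promoter_beta <- function(promoters, probe_beta) {
  if (is.null(rownames(probe_beta))) abort("`probe_beta` needs probe rownames")
  out <- matrix(NA_real_, nrow = nrow(promoters), ncol = ncol(probe_beta),
                dimnames = list(promoters$promoter_id, colnames(probe_beta)))
  for (i in seq_len(nrow(promoters))) {
    rows <- intersect(promoters$probe_ids[[i]], rownames(probe_beta))
    if (length(rows) == 0) {
      abort(sprintf("promoter %s has no probes in the beta matrix",
                    promoters$promoter_id[i]))
    }
    out[i, ] <- colMeans(probe_beta[rows, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Bidirectional gene/promoter mapping
#'
#' Merged promoters may carry several genes and genes may own several
#' promoters; both directions are returned as tidy tables.
#'
#' @param promoters Output of [curate_promoters()].
#' @return List with `by_gene` (tibble `gene_id`, `promoter_id`) and
#'   `by_promoter` (the same rows keyed the other way).
#' @export
map_genes <- function(promoters) {
  pairs <- promoters |>
    select("promoter_id", "gene_ids") |>
    tidyr::unnest_longer("gene_ids", values_to = "gene_id") |>
    select("gene_id", "promoter_id")
  list(by_gene = arrange(pairs, .data$gene_id, .data$promoter_id),
       by_promoter = arrange(pairs, .data$promoter_id, .data$gene_id))
}
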