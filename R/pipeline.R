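# Config-driven orchestration: simulate (or load) -> curate -> PRC2 annotate
# -> DE -> class calls -> downstream statistics, with one reproducible
# results bundle.

default_thresholds <- function() {
  list(
    beta_low = 0.2, beta_low_frac = 0.9, beta_high = 0.3,
    beta_high_frac = 0.15,
    padj = 0.05, lfc = 1,
    detect_frac = 0.8, fpkm_cutoff = 1, fpkm_frac = 0.5,
    normal_fpkm_gate = 4,
    restricted_fc = 2,
    min_normal_samples = 5,
    h3k27me3_states = c(10, 11, 13)
  )
}

#' Default pipeline configuration
#'
#' @param seed Integer seed driving every stage.
#' @param simulate A [sim_config()] (or list of overrides for it); set to
#'   `NULL` when `inputs` point at files on disk.
#' @param inputs Named list of file paths (`counts`, `beta`, `samples`,
#'   `gene_lengths`, `tss`, `probes`, `cgi`, `states`, `ezh2`, `suz12`,
#'   `lads`, `links`, `gene_sets`) used when `simulate` is `NULL`.
#' @param thresholds Named list of stage thresholds; defaults are the study
#'   values (see [validate_config()]).
#' @param out_dir Optional output directory for the results bundle.
#' @return A list of class `cgip_config`.
#' @export
pipeline_config <- function(seed = 1L, simulate = sim_config(seed = seed),
                            inputs = NULL, thresholds = list(),
                            out_dir = NULL) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  cfg <- list(seed = as.integer(seed), simulate = simulate, inputs = inputs,
              thresholds = th, out_dir = out_dir)
  class(cfg) <- "cgip_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns a tibble of findings: `level` (`"error"` or `"warning"`) and
#' `message`. Errors cover missing input files and thresholds outside their
#' domain; non-default thresholds produce warnings (e.g. the FPKM > 4
#' robustness setting).
#'
#' @param config A `cgip_config`, or a path to a YAML file with the same
#'   fields.
#' @return Tibble of findings (zero rows when the config is clean).
#' @export
validate_config <- function(config) {
  config <- load_config(config)
  th <- config$thresholds
  defaults <- default_thresholds()
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1]] <<- tibble(level = level, message = msg)
  }
  fracs <- c("beta_low_frac", "beta_high_frac", "detect_frac", "fpkm_frac")
  for (f in fracs) {
    if (th[[f]] < 0 || th[[f]] > 1) {
      note("error", sprintf("threshold %s = %s outside [0, 1]", f, th[[f]]))
    }
  }
  if (th$padj <= 0 || th$padj > 1) note("error", "padj threshold outside (0, 1]")
  if (th$beta_low < 0 || th$beta_low > 1 || th$beta_high < 0 ||
        th$beta_high > 1) {
    note("error", "beta thresholds must lie in [0, 1]")
  }
  for (f in setdiff(names(defaults), "h3k27me3_states")) {
    if (!isTRUE(all.equal(th[[f]], defaults[[f]]))) {
      lab <- if (f == "fpkm_cutoff" && isTRUE(all.equal(th[[f]], 4))) {
        "non-default (robustness setting: tumor FPKM > 4)"
      } else "non-default"
      note("warning", sprintf("threshold %s = %s is %s", f, th[[f]], lab))
    }
  }
  if (is.null(config$simulate)) {
    if (is.null(config$inputs)) {
      note("error", "neither a simulate block nor input paths given")
    } else {
      for (nm in names(config$inputs)) {
        paths <- unlist(config$inputs[[nm]], use.names = FALSE)
        for (pp in paths) {
          if (!file.exists(pp)) {
            note("error", sprintf("input '%s' not found: %s", nm, pp))
          }
        }
      }
    }
  }
  if (length(findings) == 0) {
    return(tibble(level = character(), message = character()))
  }
  bind_rows(findings)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    raw <- yaml::read_yaml(config)
    sim <- if (!is.null(raw$simulate)) {
      do.call(sim_config, utils::modifyList(list(seed = raw$seed %||% 1L),
                                            raw$simulate))
    } else NULL
    config <- pipeline_config(seed = raw$seed %||% 1L, simulate = sim,
                              inputs = raw$inputs,
                              thresholds = raw$thresholds %||% list(),
                              out_dir = raw$out_dir)
  }
  if (!inherits(config, "cgip_config")) {
    if (is.list(config)) {
      config <- do.call(pipeline_config, config)
    } else {
      abort("config must be a cgip_config, a list or a YAML path")
    }
  }
  config
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!inherits(sim, "cgip_sim_config")) {
      sim <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                   sim))
    }
    ann <- simulate_annotation(sim)
    coh <- simulate_cohort(sim, ann)
    list(
      counts = coh$counts, beta = coh$beta, samples = coh$samples,
      gene_lengths = coh$gene_lengths, tss = ann$tss,
      probes = select(ann$probes, "probe_id", "chrom", "position"),
      cgi = ann$cgi, states = ann$states, ezh2 = ann$ezh2,
      suz12 = ann$suz12, lads = ann$lads, links = ann$links,
      motifs = ann$motifs, gene_sets = ann$gene_sets,
      tf_genes = ann$tf_genes, truth = coh$truth, annotation = ann
    )
  } else {
    ip <- config$inputs
    need <- setdiff(c("counts", "beta", "samples", "gene_lengths", "tss",
                      "probes", "cgi", "states", "ezh2", "suz12", "lads",
                      "links", "gene_sets"), names(ip))
    if (length(need) > 0) {
      abort(paste0("missing input path(s): ", paste(need, collapse = ", ")))
    }
    motifs <- list()
    if (!is.null(ip$motifs)) {
      motifs <- lapply(ip$motifs, read_bed)
      names(motifs) <- names(ip$motifs)
    }
    list(
      counts = read_count_matrix(ip$counts), beta = read_beta_matrix(ip$beta),
      samples = read_sample_sheet(ip$samples),
      gene_lengths = read_gene_lengths(ip$gene_lengths),
      tss = read_tss_table(ip$tss), probes = read_probe_manifest(ip$probes),
      cgi = read_bed(ip$cgi), states = read_bed(ip$states),
      ezh2 = read_bed(ip$ezh2), suz12 = read_bed(ip$suz12),
      lads = read_bed(ip$lads), links = read_link_table(ip$links),
      motifs = motifs, gene_sets = read_gmt(ip$gene_sets),
      tf_genes = NULL, truth = NULL, annotation = NULL
    )
  }
}

#' Run the full classification pipeline
#'
#' Executes simulate/load -> promoter curation -> PRC2 annotation -> per-type
#' differential expression, hypermethylation calling and class assembly ->
#' plasticity, cancer-type-restricted, PCA-ratio, LAD, enhancer-link and
#' gene-set enrichment statistics. Deterministic given config + seed. Cancer
#' types with fewer than `min_normal_samples` nonmalignant samples are
#' skipped with a warning.
#'
#' @param config A `cgip_config` from [pipeline_config()], a plain list of
#'   its fields, or a YAML path.
#' @return A list of class `cgip_result`: `promoters`, `class_calls`,
#'   `de_tables`, `plasticity`, `restricted`, `pca_ratios`, `lad_fractions`,
#'   `enhancers`, `set_enrichment`, `motif_enrichment`, `summary`, `truth`
#'   (when simulated), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- load_config(config)
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    abort(paste0("invalid config: ",
                 paste(findings$message[findings$level == "error"],
                       collapse = "; ")))
  }
  th <- config$thresholds
  inp <- load_pipeline_inputs(config)

  promoters <- curate_promoters(inp$tss, inp$probes, inp$cgi) |>
    classify_prc2(inp$states, inp$ezh2, inp$suz12,
                  h3k27me3_states = th$h3k27me3_states)
  gclass <- gene_prc2_class(promoters)
  pbeta <- promoter_beta(promoters, inp$beta)
  fpkm <- compute_fpkm(inp$counts, inp$gene_lengths)

  types <- unique(inp$samples$cancer_type)
  calls <- list(); de_tables <- list()
  for (t in types) {
    st <- filter(inp$samples, .data$cancer_type == t)
    normal_ids <- st$sample_id[st$condition == "normal"]
    tumor_ids <- st$sample_id[st$condition == "tumor"]
    if (length(normal_ids) < th$min_normal_samples) {
      warn(sprintf("cancer type %s skipped: %d nonmalignant sample(s) < %d",
                   t, length(normal_ids), th$min_normal_samples))
      next
    }
    pf <- expression_filter(inp$counts, fpkm, normal_ids, tumor_ids,
                            detect_frac = th$detect_frac,
                            fpkm_cutoff = th$fpkm_cutoff,
                            fpkm_frac = th$fpkm_frac)
    de <- nb_two_group_test(inp$counts, normal_ids, tumor_ids,
                            passed_filter = pf)
    hyper <- call_hypermethylated_promoters(
      pbeta, normal_ids, tumor_ids, low = th$beta_low,
      low_frac = th$beta_low_frac, high = th$beta_high,
      high_frac = th$beta_high_frac
    )
    pos_genes <- gclass$gene_id[gclass$gene_prc2 == "PRC2_POS"]
    gated <- normal_expression_gate(pos_genes, fpkm, normal_ids,
                                    cutoff = th$normal_fpkm_gate)
    calls[[t]] <- assemble_gene_classes(promoters, hyper, de, gated, t,
                                        padj_cutoff = th$padj,
                                        lfc_cutoff = th$lfc)
    de_tables[[t]] <- de
  }
  if (length(calls) == 0) abort("no cancer type had enough nonmalignant samples")
  class_calls <- bind_rows(calls)

  tumor_sheet <- filter(inp$samples,
                        .data$condition == "tumor",
                        .data$cancer_type %in% names(calls))
  tumor_types <- stats::setNames(tumor_sheet$cancer_type,
                                 tumor_sheet$sample_id)

  plasticity <- if (length(calls) >= 2) plastic_genes(class_calls) else NULL

  up_pos <- unique(class_calls$gene_id[class_calls$label == "UP_PRC2"])
  up_neg <- unique(class_calls$gene_id[class_calls$label == "UP_PRC2NEG"])

  restricted <- purrr::map_dfr(names(calls), function(t) {
    set <- class_calls$gene_id[class_calls$cancer_type == t &
                                 class_calls$label == "UP_PRC2"]
    if (length(set) == 0) return(tibble())
    cancer_restricted_genes(fpkm[, names(tumor_types), drop = FALSE],
                            tumor_types, set, t,
                            fc_cutoff = th$restricted_fc,
                            counts = inp$counts[, names(tumor_types),
                                                drop = FALSE]) |>
      mutate(cancer_type = t, .before = 1)
  })

  pca_ratios <- tibble(
    gene_class = c("UP_PRC2", "UP_PRC2NEG"),
    ratio = c(
      if (length(up_pos) >= 2 && length(calls) >= 2)
        pca_distance_ratio(fpkm[, names(tumor_types), drop = FALSE],
                           tumor_types, up_pos) else NA_real_,
      if (length(up_neg) >= 2 && length(calls) >= 2)
        pca_distance_ratio(fpkm[, names(tumor_types), drop = FALSE],
                           tumor_types, up_neg) else NA_real_
    )
  )

  promoters_by_class <- class_promoters(promoters, class_calls)
  lad_fractions <- lad_fraction_by_class(promoters_by_class, inp$lads) |>
    rename(gene_class = "class")

  prc2_genes <- gclass$gene_id[gclass$gene_prc2 == "PRC2_POS"]
  prc2neg_genes <- gclass$gene_id[gclass$gene_prc2 == "PRC2_NEG"]
  enhancers <- enhancers_per_gene(inp$links,
                                  list(PRC2_POS = prc2_genes,
                                       PRC2_NEG = prc2neg_genes))

  set_enrichment <- if (length(up_pos) > 0 && length(up_neg) > 0 &&
                          length(inp$gene_sets) > 0) {
    binomial_z_enrichment(up_pos, up_neg, inp$gene_sets)
  } else NULL

  motif_enrichment <- NULL
  if (length(inp$motifs) > 0 && length(up_pos) > 0 && length(up_neg) > 0) {
    fg_regions <- linked_regions_for_genes(inp$links, up_pos)
    bg_regions <- linked_regions_for_genes(
      inp$links, setdiff(up_neg, up_pos))
    if (nrow(fg_regions) > 0 && nrow(bg_regions) > 0) {
      tf_med <- vapply(names(inp$motifs), function(tf) {
        if (tf %in% rownames(fpkm)) {
          stats::median(fpkm[tf, names(tumor_types)])
        } else NA_real_
      }, numeric(1))
      tf_med <- tf_med[!is.na(tf_med)]
      motif_enrichment <- hypergeom_region_enrichment(
        fg_regions, bg_regions, inp$motifs[names(tf_med)], tf_med
      )
    }
  }

  summary <- list(
    n_cancer_types = length(calls),
    class_counts = class_calls |>
      filter(.data$label != "NONE") |>
      dplyr::count(.data$cancer_type, .data$label),
    n_promoters = nrow(promoters),
    n_prc2_pos_promoters = sum(promoters$prc2_status == "PRC2_POS"),
    plastic = plasticity$summary,
    pca_ratios = pca_ratios,
    lad_fractions = lad_fractions,
    enhancers = enhancers
  )

  res <- list(promoters = promoters, gene_prc2 = gclass,
              class_calls = class_calls, de_tables = de_tables,
              plasticity = plasticity, restricted = restricted,
              pca_ratios = pca_ratios, lad_fractions = lad_fractions,
              enhancers = enhancers, set_enrichment = set_enrichment,
              motif_enrichment = motif_enrichment, summary = summary,
              fpkm = fpkm, samples = inp$samples, truth = inp$truth,
              config = config)
  class(res) <- "cgip_result"
  if (!is.null(config$out_dir)) write_result_bundle(res, config$out_dir)
  res
}

# promoters of genes called in each class (per spec the LAD comparison is at
# promoter level, pooled over cancer types)
class_promoters <- function(promoters, class_calls) {
  by_gene <- map_genes(promoters)$by_gene
  lapply(stats::setNames(nm = c("HYPER_PRC2", "UP_PRC2", "UP_PRC2NEG")),
         function(lb) {
           genes <- unique(class_calls$gene_id[class_calls$label == lb])
           pid <- unique(by_gene$promoter_id[by_gene$gene_id %in% genes])
           promoters[promoters$promoter_id %in% pid, , drop = FALSE]
         })
}

write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  wt <- function(x, f) {
    utils::write.table(x, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prom_flat <- res$promoters |>
    mutate(across(c("tss_ids", "gene_ids", "probe_ids"),
                  ~ vapply(.x, paste, character(1), collapse = ",")))
  wt(prom_flat, "promoters.tsv")
  wt(res$class_calls, "class_calls.tsv")
  for (t in names(res$de_tables)) {
    wt(tidy(res$de_tables[[t]]), sprintf("de_%s.tsv", t))
  }
  if (!is.null(res$plasticity)) wt(res$plasticity$summary, "plasticity.tsv")
  if (nrow(res$restricted) > 0) wt(res$restricted, "restricted.tsv")
  wt(res$lad_fractions, "lad_fractions.tsv")
  wt(res$enhancers, "enhancers_per_gene.tsv")
  if (!is.null(res$set_enrichment)) wt(res$set_enrichment, "set_enrichment.tsv")
  if (!is.null(res$motif_enrichment)) {
    wt(res$motif_enrichment, "motif_enrichment.tsv")
  }
  summary_json <- res$summary
  summary_json$class_counts <- as.data.frame(summary_json$class_counts)
  jsonlite::write_json(summary_json, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  cfg <- res$config
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  yaml::write_yaml(lapply(unclass(cfg), function(x) x),
                   p("effective_config.yaml"))
  invisible(out_dir)
}

#' Score class calls against a planted truth table
#'
#' Per-class sensitivity (recall of planted (gene, cancer type) labels) and
#' precision over all genes x cancer types present in the truth table.
#'
#' @param class_calls Tibble `gene_id`, `cancer_type`, `label` (e.g.
#'   `result$class_calls`). Genes in the truth but absent from the calls
#'   count as `NONE` calls.
#' @param truth_labels Truth tibble `gene_id`, `cancer_type`, `label`.
#' @return Tibble `label`, `n_truth`, `n_called`, `tp`, `sensitivity`,
#'   `precision`.
#' @export
score_against_truth <- function(class_calls, truth_labels) {
  joined <- truth_labels |>
    rename(truth = "label") |>
    left_join(select(class_calls, "gene_id", "cancer_type", called = "label"),
              by = c("gene_id", "cancer_type")) |>
    mutate(called = dplyr::coalesce(.data$called, "NONE"))
  labs <- setdiff(union(joined$truth, joined$called), "NONE")
  purrr::map_dfr(sort(labs), function(lb) {
    tp <- sum(joined$truth == lb & joined$called == lb)
    nt <- sum(joined$truth == lb)
    nc <- sum(joined$called == lb)
    tibble(label = lb, n_truth = nt, n_called = nc, tp = tp,
           sensitivity = if (nt > 0) tp / nt else NA_real_,
           precision = if (nc > 0) tp / nc else NA_real_)
  })
}

#' @export
print.cgip_result <- function(x, ...) {
  cat("<cgip_result>\n")
  cat(sprintf("  cancer types analyzed: %d\n", x$summary$n_cancer_types))
  cat(sprintf("  curated CGI promoters: %d (PRC2+: %d)\n",
              x$summary$n_promoters, x$summary$n_prc2_pos_promoters))
  cc <- x$summary$class_counts
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %s %-13s %d genes\n", cc$cancer_type[i], cc$label[i],
                cc$n[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cgip_result <- function(x, ...) {
  tibble(
    n_cancer_types = x$summary$n_cancer_types,
    n_promoters = x$summary$n_promoters,
    n_prc2_pos_promoters = x$summary$n_prc2_pos_promoters,
    n_hyper_prc2 = sum(x$class_calls$label == "HYPER_PRC2"),
    n_up_prc2 = sum(x$class_calls$label == "UP_PRC2"),
    n_up_prc2neg = sum(x$class_calls$label == "UP_PRC2NEG"),
    pct_plastic_prc2 = if (!is.null(x$plasticity)) {
      s <- x$plasticity$summary
      sum(s$n_plastic[s$prc2_class == "PRC2_POS"]) /
        max(1, sum(s$n_upregulated[s$prc2_class == "PRC2_POS"]))
    } else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.cgip_result <- function(x, ...) {
  x$class_calls
}
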