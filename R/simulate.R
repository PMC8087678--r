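# Synthetic multi-cancer cohort with planted ground truth.
#
# The generator lays genes out on a two-chromosome toy genome, plants
# hypermethylated / upregulated / plastic / cancer-type-restricted genes, and
# emits every annotation shape the pipeline consumes (TSS table, CGI / state /
# peak / LAD BEDs, probe manifest, enhancer links, motif occurrences, gene
# sets) plus count and beta matrices. All randomness flows from config$seed.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 3 cancer types, 2,000 genes, 10 nonmalignant and 40 tumor samples
#' per type, NB dispersion 0.05, probe-level beta drawn from Beta(2,30)
#' (unmethylated, mean 0.0625) or Beta(20,6) (methylated, mean 0.77).
#'
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param n_cancer_types Number of cancer types.
#' @param n_normal,n_tumor Samples per cancer type.
#' @param n_genes Number of genes on the toy genome.
#' @param gene_length_range Range (bp) gene lengths are drawn from.
#' @param library_size_mean Expected total counts per sample.
#' @param library_size_cv Lognormal sdlog of per-sample library factors.
#' @param nb_dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param beta_unmeth,beta_meth Beta(a,b) parameters for unmethylated /
#'   methylated probes.
#' @param f_hyper_prc2,f_up_prc2,f_up_prc2neg,f_plastic Planted fractions of
#'   `n_genes`.
#' @param f_restricted Named fractions (`prc2`, `prc2neg`) of planted
#'   upregulated genes restricted to exactly one cancer type; the rest are
#'   upregulated in every type.
#' @param fc_up_prc2,fc_up_prc2neg Planted tumor/normal fold changes.
#' @param hyper_penetrance Fraction of tumors whose beta shifts for a planted
#'   hypermethylated gene.
#' @param hyper_down_range Tumor expression multiplier range for
#'   hypermethylated genes (slight downregulation).
#' @param prc2_fraction Fraction of genes given PRC2+ promoters.
#' @param cgi_fraction Fraction of genes whose promoter overlaps a CGI.
#' @param ambiguous_fraction Fraction of genes given bivalent chromatin but no
#'   EZH2/SUZ12 peak (PRC2 status ambiguous).
#' @param lad_fraction Named per-role probabilities (`hyper`, `up_prc2`,
#'   `up_prc2neg`, `other`) that a promoter sits inside a LAD.
#' @param enh_mean Named Poisson means (`prc2`, `prc2neg`) for enhancer links
#'   per gene.
#' @param program_strength,program_fraction One cancer type's tumors share a
#'   weak global expression program (`program_strength` fold on a random
#'   `program_fraction` of genes) so sample clustering is non-trivial.
#' @param tf_coupling,tf_activity_sd Coupling exponent and lognormal activity
#'   sd tying designated TF-target genes to the TF's expression in the first
#'   cancer type's tumors.
#' @param probes_per_promoter,tss_per_gene Integer ranges.
#' @return A list of class `cgip_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cancer_types = 3L,
                       n_normal = 10L,
                       n_tumor = 40L,
                       n_genes = 2000L,
                       gene_length_range = c(800L, 2500L),
                       library_size_mean = 1e7,
                       library_size_cv = 0.15,
                       nb_dispersion = 0.05,
                       beta_unmeth = c(2, 30),
                       beta_meth = c(20, 6),
                       f_hyper_prc2 = 0.10,
                       f_up_prc2 = 0.06,
                       f_up_prc2neg = 0.10,
                       f_plastic = 0.02,
                       f_restricted = c(prc2 = 0.7, prc2neg = 0.3),
                       fc_up_prc2 = 4,
                       fc_up_prc2neg = 2.5,
                       hyper_penetrance = 0.4,
                       hyper_down_range = c(0.7, 1.0),
                       prc2_fraction = 0.25,
                       cgi_fraction = 0.95,
                       ambiguous_fraction = 0.015,
                       lad_fraction = c(hyper = 0.4, up_prc2 = 0.15,
                                        up_prc2neg = 0.098, other = 0.1),
                       enh_mean = c(prc2 = 2.9, prc2neg = 1.9),
                       program_strength = 1.3,
                       program_fraction = 0.1,
                       tf_coupling = 0.7,
                       tf_activity_sd = 0.6,
                       probes_per_promoter = c(2L, 6L),
                       tss_per_gene = c(1L, 3L)) {
  cfg <- as.list(environment())
  class(cfg) <- "cgip_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  planted <- cfg$f_hyper_prc2 + cfg$f_up_prc2 + cfg$f_up_prc2neg + cfg$f_plastic
  if (planted > 1) abort("planted fractions must sum to <= 1")
  fr <- c(cfg$f_hyper_prc2, cfg$f_up_prc2, cfg$f_up_prc2neg, cfg$f_plastic,
          cfg$f_restricted, cfg$hyper_penetrance, cfg$prc2_fraction,
          cfg$cgi_fraction, cfg$ambiguous_fraction, cfg$lad_fraction,
          cfg$program_fraction)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (any(c(cfg$n_cancer_types, cfg$n_normal, cfg$n_tumor, cfg$n_genes) < 1)) {
    abort("counts (types, samples, genes) must be positive")
  }
  prc2_planted <- cfg$f_hyper_prc2 + cfg$f_up_prc2 + cfg$f_plastic
  if (prc2_planted > cfg$prc2_fraction) {
    abort("PRC2+ planted fractions exceed prc2_fraction")
  }
  if (cfg$f_up_prc2neg > cfg$cgi_fraction - cfg$prc2_fraction) {
    abort("f_up_prc2neg exceeds the PRC2- CGI pool")
  }
  invisible(cfg)
}

GENE_SLOT_BP <- 3000L

#' Simulate the toy annotation bundle
#'
#' Lays out genes over two chromosomes (1-3 TSSs each, 2-6 probes per
#' promoter), assigns CGI/PRC2/LAD status and planted roles, and emits the
#' chromatin-state segments, EZH2/SUZ12 peaks, LADs, enhancer-to-gene links,
#' per-TF motif occurrences and gene sets consistent with those roles. Every
#' PRC2+ promoter overlaps both a bivalent/repressed-state segment and a
#' subunit peak; PRC2- promoters overlap neither.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genes`, `tss`, `probes`, `cgi`, `states`,
#'   `ezh2`, `suz12`, `lads`, `links`, `motifs`, `gene_sets`, `tf_genes`,
#'   `config`.
#' @export
simulate_annotation <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_annotation_impl(config))
}

simulate_annotation_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  chrom <- ifelse(seq_len(n) %% 2L == 1L, "chr1", "chr2")
  slot <- (seq_len(n) + 1L) %/% 2L
  tss0 <- 2000L + (slot - 1L) * GENE_SLOT_BP
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- as.integer(round(stats::runif(n, cfg$gene_length_range[1],
                                       cfg$gene_length_range[2])))

  # status pools -------------------------------------------------------------
  cgi_genes <- sort(sample.int(n, round(cfg$cgi_fraction * n)))
  prc2_pos <- sort(sample(cgi_genes, round(cfg$prc2_fraction * n)))
  ambig <- sort(sample(setdiff(cgi_genes, prc2_pos),
                       round(cfg$ambiguous_fraction * n)))
  prc2_neg <- setdiff(cgi_genes, c(prc2_pos, ambig))

  # planted roles (PRC2+ roles disjoint within the PRC2+ pool) ---------------
  pool_pos <- sample(prc2_pos)
  n_hyper <- round(cfg$f_hyper_prc2 * n)
  n_up <- round(cfg$f_up_prc2 * n)
  n_plastic <- round(cfg$f_plastic * n)
  hyper_genes <- pool_pos[seq_len(n_hyper)]
  up_prc2_genes <- pool_pos[n_hyper + seq_len(n_up)]
  plastic_genes <- pool_pos[n_hyper + n_up + seq_len(n_plastic)]
  n_upn <- round(cfg$f_up_prc2neg * n)
  up_prc2neg_genes <- sample(prc2_neg, n_upn)

  role <- rep("none", n)
  role[hyper_genes] <- "hyper"
  role[up_prc2_genes] <- "up_prc2"
  role[plastic_genes] <- "plastic"
  role[up_prc2neg_genes] <- "up_prc2neg"

  # target cancer types: restricted genes get exactly one type ---------------
  ntypes <- cfg$n_cancer_types
  target_type <- rep(NA_integer_, n)
  assign_targets <- function(idx, frac) {
    idx <- sample(idx)
    n_res <- round(frac * length(idx))
    res <- idx[seq_len(n_res)]
    target_type[res] <<- rep_len(seq_len(ntypes), n_res)
    target_type[setdiff(idx, res)] <<- 0L # 0 = upregulated in every type
  }
  if (n_up > 0) assign_targets(up_prc2_genes, cfg$f_restricted[["prc2"]])
  if (n_upn > 0) assign_targets(up_prc2neg_genes, cfg$f_restricted[["prc2neg"]])

  up_type <- rep(NA_integer_, n)
  hyper_type <- rep(NA_integer_, n)
  if (n_plastic > 0 && ntypes >= 2) {
    pairs <- expand.grid(a = seq_len(ntypes), b = seq_len(ntypes))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    pick <- rep_len(seq_len(nrow(pairs)), n_plastic)
    up_type[plastic_genes] <- pairs$a[pick]
    hyper_type[plastic_genes] <- pairs$b[pick]
  }

  lad_p <- cfg$lad_fraction[["other"]] + numeric(n)
  lad_p[role == "hyper"] <- cfg$lad_fraction[["hyper"]]
  lad_p[role %in% c("up_prc2", "plastic")] <- cfg$lad_fraction[["up_prc2"]]
  lad_p[role == "up_prc2neg"] <- cfg$lad_fraction[["up_prc2neg"]]
  in_lad <- stats::runif(n) < lad_p

  genes <- tibble(
    gene_id = gene_id, chrom = chrom, tss0 = tss0, strand = strand,
    length = len,
    is_cgi = seq_len(n) %in% cgi_genes,
    prc2_truth = dplyr::case_when(
      seq_len(n) %in% prc2_pos ~ "POS",
      seq_len(n) %in% ambig ~ "AMBIG",
      seq_len(n) %in% prc2_neg ~ "NEG",
      TRUE ~ "NONCGI"
    ),
    role = role, target_type = target_type,
    up_type = up_type, hyper_type = hyper_type,
    in_lad = in_lad
  )

  # TSSs and probes -----------------------------------------------------------
  k_tss <- sample(seq(cfg$tss_per_gene[1], cfg$tss_per_gene[2]), n,
                  replace = TRUE)
  # non-planted genes with >1 TSS may get a private probe set for the last
  # TSS, exercising the multi-promoter code path
  split_gene <- role == "none" & k_tss >= 2 & stats::runif(n) < 0.05

  tss_rows <- vector("list", n)
  probe_rows <- vector("list", n)
  for (i in seq_len(n)) {
    offs <- if (k_tss[i] > 1) {
      c(0L, sort(sample(30:240, k_tss[i] - 1L)))
    } else 0L
    pos0 <- tss0[i] + offs
    w <- promoter_window(tibble(chrom = chrom[i], position = pos0,
                                strand = strand[i]))
    core_lo <- max(w$start); core_hi <- min(w$end)
    np <- sample(seq(cfg$probes_per_promoter[1], cfg$probes_per_promoter[2]), 1)
    ppos <- sort(sample(seq(core_lo, core_hi - 1L), np))
    pid <- sprintf("cg_%s_%02d", gene_id[i], seq_len(np))
    if (split_gene[i]) {
      # probes private to the downstream-most window
      last <- which.max(w$end)
      extra_lo <- max(w$end[-last]); extra_hi <- w$end[last]
      if (extra_hi - extra_lo >= 2) {
        epos <- sort(sample(seq(extra_lo, extra_hi - 1L), 2))
        ppos <- c(ppos, epos)
        pid <- c(pid, sprintf("cg_%s_x%d", gene_id[i], 1:2))
      }
    }
    tss_rows[[i]] <- tibble(
      tss_id = sprintf("tss_%s_%d", gene_id[i], seq_len(k_tss[i])),
      gene_id = gene_id[i], chrom = chrom[i],
      position = pos0 + 1L, # 1-based in the TSS table
      strand = strand[i]
    )
    probe_rows[[i]] <- tibble(probe_id = pid, chrom = chrom[i],
                              position = ppos + 1L, gene_id = gene_id[i])
  }
  tss_tbl <- bind_rows(tss_rows)
  probe_tbl <- bind_rows(probe_rows)

  # decoy promoters on excluded chromosomes ----------------------------------
  decoys <- tibble(
    tss_id = sprintf("tss_decoy_%d", 1:7),
    gene_id = sprintf("gene_decoy_%d", 1:7),
    chrom = c(rep("chrY", 5), rep("chrM", 2)),
    position = 1000L + (0:6) * 2000L,
    strand = rep(c("+", "-"), length.out = 7)
  )
  tss_tbl <- bind_rows(tss_tbl, decoys)
  probe_tbl <- bind_rows(probe_tbl, tibble(
    probe_id = sprintf("cg_decoy_%d", 1:14),
    chrom = rep(decoys$chrom, each = 2),
    position = rep(decoys$position, each = 2) + c(-50L, 50L),
    gene_id = rep(decoys$gene_id, each = 2)
  ))

  win_lo <- tss0 - 550L
  win_hi <- tss0 + 800L
  cgi <- tibble(chrom = chrom[cgi_genes],
                start = pmax(0L, win_lo[cgi_genes]), end = win_hi[cgi_genes],
                name = sprintf("cgi_%s", gene_id[cgi_genes]))

  biv_labels <- c("10_TssBiv", "11_BivFlnk", "13_ReprPC")
  biv_idx <- sort(c(prc2_pos, ambig))
  states <- tibble(
    chrom = chrom[biv_idx], start = pmax(0L, tss0[biv_idx] - 400L),
    end = tss0[biv_idx] + 600L,
    name = sample(biv_labels, length(biv_idx), replace = TRUE)
  )
  active_idx <- prc2_neg[stats::runif(length(prc2_neg)) < 0.5]
  states <- bind_rows(states, tibble(
    chrom = chrom[active_idx], start = pmax(0L, tss0[active_idx] - 400L),
    end = tss0[active_idx] + 600L, name = "1_TssA"
  )) |> arrange(.data$chrom, .data$start)

  which_peak <- sample(c("ezh2", "suz12", "both"), length(prc2_pos),
                       replace = TRUE, prob = c(0.4, 0.3, 0.3))
  peak_tbl <- function(idx) {
    tibble(chrom = chrom[idx], start = pmax(0L, tss0[idx] - 100L),
           end = tss0[idx] + 200L, name = sprintf("peak_%s", gene_id[idx]))
  }
  ezh2 <- peak_tbl(prc2_pos[which_peak %in% c("ezh2", "both")])
  suz12 <- peak_tbl(prc2_pos[which_peak %in% c("suz12", "both")])

  lad_idx <- which(in_lad)
  lads <- tibble(chrom = chrom[lad_idx], start = pmax(0L, tss0[lad_idx] - 600L),
                 end = tss0[lad_idx] + 900L,
                 name = sprintf("lad_%s", gene_id[lad_idx]))

  # enhancer-to-gene links ----------------------------------------------------
  enh_mu <- ifelse(seq_len(n) %in% prc2_pos, cfg$enh_mean[["prc2"]],
                   cfg$enh_mean[["prc2neg"]])
  n_links <- stats::rpois(n, enh_mu)
  link_rows <- lapply(which(n_links > 0), function(i) {
    l <- seq_len(n_links[i])
    tibble(peak_id = sprintf("enh_%s_%d", gene_id[i], l),
           chrom = chrom[i],
           start = tss0[i] + 1200L + (l - 1L) * 150L,
           end = tss0[i] + 1200L + (l - 1L) * 150L + 100L,
           gene_id = gene_id[i],
           correlation = round(stats::runif(n_links[i], 0.2, 0.9), 3))
  })
  links <- if (length(link_rows) > 0) bind_rows(link_rows) else {
    tibble(peak_id = character(), chrom = character(), start = integer(),
           end = integer(), gene_id = character(), correlation = numeric())
  }

  # TFs and motif occurrences -------------------------------------------------
  tf_pool <- setdiff(prc2_neg, up_prc2neg_genes)
  tf_idx <- sample(tf_pool, 3)
  tf_genes <- c(active = gene_id[tf_idx[1]], null = gene_id[tf_idx[2]],
                lowexpr = gene_id[tf_idx[3]])
  pick_targets <- function(pool, frac) {
    if (length(pool) == 0) return(character(0))
    gene_id[sample(pool, round(frac * length(pool)))]
  }
  tf1_targets <- pick_targets(up_prc2_genes, 0.6)
  tf3_targets <- pick_targets(up_prc2_genes, 0.5)
  plant_motifs <- function(targets, p_target = 0.7, p_bg = 0.08) {
    hit <- ifelse(links$gene_id %in% targets, p_target, p_bg)
    occ <- links[stats::runif(nrow(links)) < hit, , drop = FALSE]
    tibble(chrom = occ$chrom, start = occ$start + 45L, end = occ$start + 55L,
           name = occ$peak_id)
  }
  motifs <- list(plant_motifs(tf1_targets),
                 plant_motifs(character(0), p_bg = 0.15),
                 plant_motifs(tf3_targets))
  names(motifs) <- unname(tf_genes)

  # gene sets ------------------------------------------------------------------
  up_pos_ids <- gene_id[c(up_prc2_genes, plastic_genes)]
  up_neg_ids <- gene_id[up_prc2neg_genes]
  other_ids <- setdiff(gene_id, c(up_pos_ids, up_neg_ids))
  gene_sets <- list(
    SET_EMT_LIKE = unique(c(sample(up_pos_ids, round(0.5 * length(up_pos_ids))),
                            sample(other_ids, 30))),
    SET_CELL_CYCLE_LIKE = unique(c(sample(up_neg_ids,
                                          round(0.5 * length(up_neg_ids))),
                                   sample(other_ids, 30)))
  )
  for (k in 1:6) {
    gene_sets[[sprintf("SET_RANDOM_%d", k)]] <- sample(gene_id, 50)
  }

  list(genes = genes, tss = tss_tbl, probes = probe_tbl, cgi = cgi,
       states = states, ezh2 = ezh2, suz12 = suz12, lads = lads,
       links = links, motifs = motifs, gene_sets = gene_sets,
       tf_genes = tf_genes,
       tf_targets = list(active = tf1_targets, lowexpr = tf3_targets),
       config = cfg)
}

#' Simulate the multi-cancer cohort matrices
#'
#' Draws NB counts and probe-level beta values consistent with the roles
#' planted by [simulate_annotation()]. Planted upregulated genes multiply the
#' tumor mean by the configured fold change in their target cancer type(s);
#' planted hypermethylated genes draw beta from the methylated Beta
#' distribution in `hyper_penetrance` of tumors of the affected type and have
#' tumor expression equal to or up to 30% below normal; plastic genes are
#' upregulated in one type and hypermethylated in another.
#'
#' @param config A [sim_config()] (must match the one used for `annotation`).
#' @param annotation Output of [simulate_annotation()].
#' @return A list of class `cgip_cohort` with `counts` (genes x samples),
#'   `beta` (probes x samples), `samples` (sample sheet), `gene_lengths`
#'   (named vector), `truth` (per gene x cancer type labels plus gene flags),
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), annotation) {
  validate_sim_config(config)
  withr::with_seed((config$seed %% 1000000L) + 500009L,
                   simulate_cohort_impl(config, annotation))
}

simulate_cohort_impl <- function(cfg, ann) {
  g <- ann$genes
  n <- nrow(g)
  ntypes <- cfg$n_cancer_types
  types <- sprintf("CT%d", seq_len(ntypes))

  samples <- purrr::map_dfr(seq_len(ntypes), function(t) {
    tibble(
      sample_id = c(sprintf("%s_N%02d", types[t], seq_len(cfg$n_normal)),
                    sprintf("%s_T%02d", types[t], seq_len(cfg$n_tumor))),
      cancer_type = types[t],
      condition = c(rep("normal", cfg$n_normal), rep("tumor", cfg$n_tumor))
    )
  })
  ns <- nrow(samples)

  # baseline FPKM: PRC2+ low (FPKM < 4 in normals); the PRC2-/non-CGI pool is
  # log-uniform and rescaled so total FPKM*length mass is 1e9, making realized
  # FPKM agree with the designed values the thresholds refer to
  base_fpkm <- numeric(n)
  is_pos <- g$prc2_truth %in% c("POS", "AMBIG")
  planted_up_pos <- g$role %in% c("up_prc2", "plastic")
  base_fpkm[is_pos] <- stats::runif(sum(is_pos), 0.2, 3.5)
  base_fpkm[g$role == "hyper"] <- stats::runif(sum(g$role == "hyper"), 0.5, 3.5)
  base_fpkm[planted_up_pos] <- stats::runif(sum(planted_up_pos), 1.2, 2.5)
  is_neg <- !is_pos
  base_fpkm[is_neg] <- exp(stats::runif(sum(is_neg), log(20), log(2000)))
  base_fpkm[g$role == "up_prc2neg"] <-
    exp(stats::runif(sum(g$role == "up_prc2neg"), log(20), log(300)))
  tf_i <- match(ann$tf_genes, g$gene_id)
  base_fpkm[tf_i[1:2]] <- 40
  base_fpkm[tf_i[3]] <- 2
  scale_neg <- (1e9 - sum(base_fpkm[is_pos] * g$length[is_pos])) /
    sum(base_fpkm[is_neg] * g$length[is_neg])
  base_fpkm[is_neg] <- base_fpkm[is_neg] * scale_neg

  base_mu <- base_fpkm * g$length * cfg$library_size_mean / 1e9
  lib_factor <- stats::rlnorm(ns, 0, cfg$library_size_cv)

  truth <- tidyr::expand_grid(gene_id = g$gene_id, cancer_type = types) |>
    left_join(select(g, "gene_id", "role", "target_type", "up_type",
                     "hyper_type"), by = "gene_id") |>
    mutate(
      type_idx = match(.data$cancer_type, types),
      label = dplyr::case_when(
        role == "hyper" ~ "HYPER_PRC2",
        role == "up_prc2" & (target_type == 0L | target_type == type_idx) ~
          "UP_PRC2",
        role == "up_prc2neg" & (target_type == 0L | target_type == type_idx) ~
          "UP_PRC2NEG",
        role == "plastic" & up_type == type_idx ~ "UP_PRC2",
        role == "plastic" & hyper_type == type_idx ~ "HYPER_PRC2",
        TRUE ~ "NONE"
      )
    ) |>
    select("gene_id", "cancer_type", "label")

  truth_genes <- g |>
    mutate(
      plastic = .data$role == "plastic",
      restricted = (.data$role %in% c("up_prc2", "up_prc2neg") &
                      !is.na(.data$target_type) & .data$target_type > 0L) |
        .data$role == "plastic",
      restricted_type = dplyr::case_when(
        role %in% c("up_prc2", "up_prc2neg") & target_type > 0L ~
          types[pmax(target_type, 1L)],
        role == "plastic" ~ types[pmax(up_type, 1L)],
        TRUE ~ NA_character_
      )
    ) |>
    select("gene_id", "role", "plastic", "restricted", "restricted_type")

  # expression means ----------------------------------------------------------
  mu <- outer(base_mu, lib_factor)
  rownames(mu) <- g$gene_id
  colnames(mu) <- samples$sample_id
  tumor <- samples$condition == "tumor"
  # truth is gene-major (expand_grid): rows = gene blocks of length ntypes
  lab_mat <- matrix(truth$label, ncol = ntypes, byrow = TRUE)
  colnames(lab_mat) <- types

  hyper_down <- stats::runif(n, cfg$hyper_down_range[1], cfg$hyper_down_range[2])
  for (t in seq_len(ntypes)) {
    cols <- which(samples$cancer_type == types[t] & tumor)
    up_pos <- lab_mat[, t] == "UP_PRC2"
    up_neg <- lab_mat[, t] == "UP_PRC2NEG"
    hy <- lab_mat[, t] == "HYPER_PRC2"
    mu[up_pos, cols] <- mu[up_pos, cols] * cfg$fc_up_prc2
    mu[up_neg, cols] <- mu[up_neg, cols] * cfg$fc_up_prc2neg
    mu[hy, cols] <- mu[hy, cols] * hyper_down[hy]
  }
  # shared program in the first cancer type's tumors
  prog_genes <- sample.int(n, round(cfg$program_fraction * n))
  ct1_tumor <- which(samples$cancer_type == types[1] & tumor)
  mu[prog_genes, ct1_tumor] <- mu[prog_genes, ct1_tumor] * cfg$program_strength
  # TF activity coupling in the first cancer type's tumors
  act <- exp(stats::rnorm(length(ct1_tumor), 0, cfg$tf_activity_sd))
  mu[tf_i[1], ct1_tumor] <- mu[tf_i[1], ct1_tumor] * act
  tgt <- match(ann$tf_targets$active, g$gene_id)
  if (length(tgt) > 0) {
    mu[tgt, ct1_tumor] <- mu[tgt, ct1_tumor] *
      matrix(rep(act^cfg$tf_coupling, each = length(tgt)), nrow = length(tgt))
  }

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = n, dimnames = dimnames(mu))

  # methylation ---------------------------------------------------------------
  pr <- ann$probes |> filter(.data$gene_id %in% g$gene_id)
  np <- nrow(pr)
  au <- cfg$beta_unmeth; am <- cfg$beta_meth
  beta <- matrix(stats::rbeta(np * ns, au[1], au[2]), nrow = np,
                 dimnames = list(pr$probe_id, samples$sample_id))
  probe_gene <- pr$gene_id
  for (t in seq_len(ntypes)) {
    cols <- which(samples$cancer_type == types[t] & tumor)
    hy_genes <- g$gene_id[lab_mat[, t] == "HYPER_PRC2"]
    if (length(hy_genes) == 0) next
    for (gid in hy_genes) {
      pen <- cols[stats::runif(length(cols)) < cfg$hyper_penetrance]
      if (length(pen) == 0) next
      rows <- which(probe_gene == gid)
      beta[rows, pen] <- stats::rbeta(length(rows) * length(pen), am[1], am[2])
    }
  }

  gl <- stats::setNames(g$length, g$gene_id)
  out <- list(counts = counts, beta = beta, samples = samples,
              gene_lengths = gl,
              truth = list(labels = truth, genes = truth_genes),
              config = cfg)
  class(out) <- "cgip_cohort"
  out
}

#' Simulate a null NB count matrix for calibration checks
#'
#' Two groups with identical NB distributions per gene; used to measure the
#' empirical type-I error of [nb_two_group_test()].
#'
#' @param n_genes Number of genes.
#' @param n_a,n_b Samples per group.
#' @param dispersion NB dispersion alpha.
#' @param mu_range Log-uniform range of per-gene means.
#' @param seed Integer seed.
#' @return List with `counts`, `group_a`, `group_b`.
#' @export
simulate_null_counts <- function(n_genes = 2000, n_a = 10, n_b = 10,
                                 dispersion = 0.1, mu_range = c(5, 500),
                                 seed = 7L) {
  withr::with_seed(seed, {
    mu <- exp(stats::runif(n_genes, log(mu_range[1]), log(mu_range[2])))
    ns <- n_a + n_b
    counts <- matrix(stats::rnbinom(n_genes * ns, mu = rep(mu, ns),
                                    size = 1 / dispersion),
                     nrow = n_genes,
                     dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                     sprintf("s%02d", seq_len(ns))))
    list(counts = counts,
         group_a = colnames(counts)[seq_len(n_a)],
         group_b = colnames(counts)[n_a + seq_len(n_b)])
  })
}

#' Write a simulated annotation + cohort to a file tree
#'
#' All files are plain text in the formats the pipeline reads (BED, TSV, GMT,
#' JSON manifest). The manifest records relative paths and a hash of the
#' configuration.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param cohort Output of [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a list, invisibly.
#' @export
write_fixture <- function(annotation, cohort, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  p <- function(...) file.path(out_dir, ...)
  write_tsv_plain <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_matrix <- function(m, path, id_col) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1] <- id_col
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_plain(annotation$tss, p("tss.tsv"))
  write_tsv_plain(select(annotation$probes, "probe_id", "chrom", "position"),
                  p("probes.tsv"))
  write_bed(annotation$cgi, p("cgi.bed"))
  write_bed(annotation$states, p("states.bed"))
  write_bed(annotation$ezh2, p("ezh2.bed"))
  write_bed(annotation$suz12, p("suz12.bed"))
  write_bed(annotation$lads, p("lads.bed"))
  write_tsv_plain(annotation$links, p("links.tsv"))
  dir.create(p("motifs"), showWarnings = FALSE)
  motif_files <- character(0)
  for (tf in names(annotation$motifs)) {
    f <- p("motifs", paste0(tf, ".bed"))
    write_bed(annotation$motifs[[tf]], f)
    motif_files <- c(motif_files, file.path("motifs", paste0(tf, ".bed")))
  }
  write_gmt(annotation$gene_sets, p("gene_sets.gmt"))
  write_matrix(cohort$counts, p("counts.tsv"), "gene_id")
  write_matrix(round(cohort$beta, 4), p("beta.tsv"), "probe_id")
  write_tsv_plain(cohort$samples, p("samples.tsv"))
  write_tsv_plain(tibble(gene_id = names(cohort$gene_lengths),
                         length = unname(cohort$gene_lengths)),
                  p("gene_lengths.tsv"))
  write_tsv_plain(cohort$truth$labels, p("truth_labels.tsv"))
  write_tsv_plain(cohort$truth$genes, p("truth_genes.tsv"))

  files <- c("tss.tsv", "probes.tsv", "cgi.bed", "states.bed", "ezh2.bed",
             "suz12.bed", "lads.bed", "links.tsv", motif_files,
             "gene_sets.gmt", "counts.tsv", "beta.tsv", "samples.tsv",
             "gene_lengths.tsv", "truth_labels.tsv", "truth_genes.tsv")
  manifest <- list(files = files,
                   config_hash = rlang::hash(unclass(annotation$config)),
                   tf_genes = as.list(annotation$tf_genes),
                   created = format(Sys.time(), "%Y-%m-%d"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
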