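beta_mat <- function(normal, tumor) {
  m <- matrix(c(normal, tumor), nrow = 1,
              dimnames = list("P1", c(sprintf("n%02d", seq_along(normal)),
                                      sprintf("t%02d", seq_along(tumor)))))
  m
}

test_that("hypermethylation calls follow both strict clauses", {
  # 10/10 normals low, 20/100 tumors high -> called (20% > 15%)
  m <- beta_mat(rep(0.05, 10), c(rep(0.6, 20), rep(0.05, 80)))
  flags <- call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                          sprintf("t%02d", 1:100))
  expect_true(flags[["P1"]])
  # 9/10 normals below 0.2: 0.9 is not > 0.9
  m <- beta_mat(c(rep(0.05, 9), 0.5), c(rep(0.6, 20), rep(0.05, 80)))
  flags <- call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                          sprintf("t%02d", 1:100))
  expect_false(flags[["P1"]])
  # exactly 15% of tumors high is not enough
  m <- beta_mat(rep(0.05, 10), c(rep(0.6, 15), rep(0.05, 85)))
  flags <- call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                          sprintf("t%02d", 1:100))
  expect_false(flags[["P1"]])
})

test_that("boundary beta values fail their strict comparisons", {
  # beta exactly 0.2 in normals does not count as 'below 0.2'
  m <- beta_mat(rep(0.2, 10), rep(0.9, 10))
  expect_false(call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                              sprintf("t%02d", 1:10))[["P1"]])
  # beta exactly 0.3 in tumors does not count as 'above 0.3'
  m <- beta_mat(rep(0.05, 10), rep(0.3, 10))
  expect_false(call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                              sprintf("t%02d", 1:10))[["P1"]])
})

test_that("missing beta values are excluded; all-missing normals give NA", {
  m <- beta_mat(c(rep(0.05, 5), rep(NA, 5)), c(rep(0.6, 2), rep(0.05, 8)))
  flags <- call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                          sprintf("t%02d", 1:10))
  expect_true(flags[["P1"]]) # 5/5 low, 2/10 high
  m <- beta_mat(rep(NA_real_, 10), rep(0.6, 10))
  flags <- call_hypermethylated_promoters(m, sprintf("n%02d", 1:10),
                                          sprintf("t%02d", 1:10))
  expect_true(is.na(flags[["P1"]]))
})

test_that("hyper flags equal brute-force evaluation on a cohort", {
  s <- small_sim()
  prom <- curate_promoters(s$ann$tss,
                           dplyr::select(s$ann$probes, "probe_id", "chrom",
                                         "position"),
                           s$ann$cgi)
  pbeta <- promoter_beta(prom, s$coh$beta)
  samples <- s$coh$samples
  nid <- samples$sample_id[samples$cancer_type == "CT2" &
                             samples$condition == "normal"]
  tid <- samples$sample_id[samples$cancer_type == "CT2" &
                             samples$condition == "tumor"]
  got <- call_hypermethylated_promoters(pbeta, nid, tid)
  want <- vapply(rownames(pbeta), function(p) {
    bn <- pbeta[p, nid]; bt <- pbeta[p, tid]
    sum(bn < 0.2, na.rm = TRUE) / sum(!is.na(bn)) > 0.9 &&
      sum(bt > 0.3, na.rm = TRUE) / sum(!is.na(bt)) > 0.15
  }, logical(1))
  expect_equal(got, want)
  expect_true(any(got)) # the planted hyper genes are visible
})

test_that("upregulation calls are strict in padj and log2fc", {
  de <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    log2fc = c(1.01, 1.5, 1.0, 1.5, 2.0),
    padj = c(0.049, 0.05, 0.01, NA, 0.01),
    passed_filter = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  up <- call_upregulated_genes(de)
  expect_true(up[["g1"]])
  expect_false(up[["g2"]]) # padj exactly 0.05
  expect_false(up[["g3"]]) # log2fc exactly 1
  expect_false(up[["g4"]]) # padj missing
  expect_false(up[["g5"]]) # filtered out
})

toy_assembly <- function() {
  prom <- tibble::tibble(
    promoter_id = sprintf("P%d", 1:6),
    gene_ids = list("g1", "g2", "g3", "g4", "g5", "g6"),
    prc2_status = c("PRC2_POS", "PRC2_POS", "PRC2_NEG", "PRC2_NEG",
                    "AMBIGUOUS", "PRC2_POS")
  )
  hyper <- c(P1 = TRUE, P2 = TRUE, P3 = FALSE, P4 = TRUE, P5 = TRUE,
             P6 = FALSE)
  de <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    log2fc = c(0.2, 1.5, 1.4, 0.1, 1.6, 1.7),
    padj = c(0.9, 0.01, 0.02, 0.8, 0.001, 0.004),
    passed_filter = TRUE
  )
  list(prom = prom, hyper = hyper, de = de)
}

test_that("gene classes are assembled per the decision pipeline", {
  fx <- toy_assembly()
  calls <- assemble_gene_classes(fx$prom, fx$hyper, fx$de,
                                 gated_genes = c("g1", "g2"),
                                 cancer_type = "CTX")
  lab <- stats::setNames(calls$label, calls$gene_id)
  expect_equal(lab[["g1"]], "HYPER_PRC2")    # hyper PRC2+, not upregulated
  expect_equal(lab[["g2"]], "UP_PRC2")       # upregulation excludes HYPER
  expect_equal(lab[["g3"]], "UP_PRC2NEG")
  expect_equal(lab[["g4"]], "HYPER_PRC2NEG")
  expect_equal(lab[["g5"]], "NONE")          # ambiguous promoters count nowhere
  expect_equal(lab[["g6"]], "NONE")          # up but PRC2+ gene failed the gate
  expect_equal(unique(calls$cancer_type), "CTX")
})

test_that("a gene in the DE table without promoters warns and stays NONE", {
  fx <- toy_assembly()
  de <- dplyr::bind_rows(fx$de,
                         tibble::tibble(gene_id = "g99", log2fc = 3,
                                        padj = 1e-5, passed_filter = TRUE))
  expect_warning(
    calls <- assemble_gene_classes(fx$prom, fx$hyper, de, c("g1", "g2"), "CTX"),
    "no curated promoter"
  )
  expect_false("g99" %in% calls$gene_id)
})

test_that("HYPER and UP labels are mutually exclusive by construction", {
  runs <- list(small_run()$class_calls, default_run()$class_calls)
  for (calls in runs) {
    per_pair <- calls |>
      dplyr::count(.data$gene_id, .data$cancer_type)
    expect_true(all(per_pair$n == 1))
    # exactly one label each, and that label cannot be both families at once
    expect_true(all(calls$label %in% c("HYPER_PRC2", "UP_PRC2", "UP_PRC2NEG",
                                       "HYPER_PRC2NEG", "NONE")))
  }
})

test_that("vacuous thresholds call every hyper-eligible pattern (saturation)", {
  fx <- toy_assembly()
  # with thresholds relaxed, the only HYPER requirement left is a flagged
  # promoter and absence of (now unreachable) upregulation
  de <- dplyr::mutate(fx$de, padj = 1, log2fc = 0)
  calls <- assemble_gene_classes(fx$prom, fx$hyper, de, character(0), "CTX",
                                 padj_cutoff = 1, lfc_cutoff = Inf)
  lab <- stats::setNames(calls$label, calls$gene_id)
  expect_equal(lab[["g1"]], "HYPER_PRC2")
  expect_equal(lab[["g2"]], "HYPER_PRC2")
  expect_equal(lab[["g4"]], "HYPER_PRC2NEG")
})

test_that("calls are invariant to sample and gene order", {
  s <- small_sim()
  prom <- curate_promoters(s$ann$tss,
                           dplyr::select(s$ann$probes, "probe_id", "chrom",
                                         "position"), s$ann$cgi)
  pbeta <- promoter_beta(prom, s$coh$beta)
  samples <- s$coh$samples
  nid <- samples$sample_id[samples$cancer_type == "CT1" &
                             samples$condition == "normal"]
  tid <- samples$sample_id[samples$cancer_type == "CT1" &
                             samples$condition == "tumor"]
  f1 <- call_hypermethylated_promoters(pbeta, nid, tid)
  f2 <- call_hypermethylated_promoters(pbeta[sample(nrow(pbeta)), ],
                                       sample(nid), sample(tid))
  expect_equal(f1[names(f2)], f2)
})
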