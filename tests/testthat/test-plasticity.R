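calls_tbl <- function(...) {
  tibble::tribble(~gene_id, ~cancer_type, ~label, ...)
}

test_that("a gene upregulated in one type and hypermethylated in another is plastic", {
  calls <- calls_tbl(
    "g1", "A", "UP_PRC2",    "g1", "B", "HYPER_PRC2",
    "g2", "A", "UP_PRC2",    "g2", "B", "UP_PRC2",
    "g3", "A", "UP_PRC2NEG", "g3", "B", "HYPER_PRC2NEG",
    "g4", "A", "UP_PRC2",    "g4", "B", "HYPER_PRC2NEG"
  )
  out <- plastic_genes(calls)
  expect_equal(out$plastic_genes$PRC2_POS, "g1")
  expect_equal(out$plastic_genes$PRC2_NEG, "g3")  # classes do not mix (g4)
  s <- out$summary
  expect_equal(s$pct_plastic[s$prc2_class == "PRC2_POS" & s$cancer_type == "A"],
               1 / 3)
  expect_error(plastic_genes(calls_tbl("g1", "A", "UP_PRC2")), "2 cancer types")
})

test_that("plastic_genes equals the brute-force pairwise definition", {
  set.seed(13)
  types <- c("A", "B", "C", "D")
  genes <- sprintf("g%03d", 1:500)
  calls <- tidyr::expand_grid(gene_id = genes, cancer_type = types) |>
    dplyr::mutate(label = sample(c("UP_PRC2", "HYPER_PRC2", "UP_PRC2NEG",
                                   "HYPER_PRC2NEG", "NONE"),
                                 dplyr::n(), replace = TRUE,
                                 prob = c(0.1, 0.1, 0.1, 0.1, 0.6)))
  out <- plastic_genes(calls)
  brute <- function(up_lab, hy_lab) {
    hits <- character(0)
    for (g in genes) {
      sub <- calls[calls$gene_id == g, ]
      for (a in types) for (b in types) {
        if (a != b &&
              any(sub$cancer_type == a & sub$label == up_lab) &&
              any(sub$cancer_type == b & sub$label == hy_lab)) {
          hits <- c(hits, g)
        }
      }
    }
    sort(unique(hits))
  }
  expect_equal(out$plastic_genes$PRC2_POS, brute("UP_PRC2", "HYPER_PRC2"))
  expect_equal(out$plastic_genes$PRC2_NEG,
               brute("UP_PRC2NEG", "HYPER_PRC2NEG"))
})

test_that("cancer-restricted genes require the fold change and significance", {
  set.seed(14)
  # 60 tumors in 3 types; g_res is 10x higher in type A only
  types <- rep(c("A", "B", "C"), each = 20)
  names(types) <- sprintf("t%02d", 1:60)
  mu <- matrix(50, nrow = 3, ncol = 60,
               dimnames = list(c("g_res", "g_flat", "g_weak"), names(types)))
  mu["g_res", types == "A"] <- 500
  mu["g_weak", types == "A"] <- 65
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 20),
                   nrow = 3, dimnames = dimnames(mu))
  expr <- counts # FPKM-like proxy, constant lengths
  out <- cancer_restricted_genes(expr, types, rownames(expr), "A",
                                 counts = counts)
  expect_true(out$restricted[out$gene_id == "g_res"])
  expect_false(out$restricted[out$gene_id == "g_flat"])
  expect_false(out$restricted[out$gene_id == "g_weak"])
  # saturation: no fold-change bar, no significance -> every gene comes back
  out <- cancer_restricted_genes(expr, types, rownames(expr), "A",
                                 fc_cutoff = 0)
  expect_true(all(out$restricted))
  expect_error(cancer_restricted_genes(expr, types[1:2], rownames(expr), "A"),
               ">= 2 tumors")
})

test_that("planted restricted genes are recalled from the default cohort", {
  res <- default_run()
  truth <- default_sim()$coh$truth$genes
  planted <- truth$gene_id[truth$restricted & !is.na(truth$restricted_type) &
                             truth$restricted_type == "CT1" &
                             truth$role %in% c("up_prc2", "plastic")]
  rec <- res$restricted |>
    dplyr::filter(.data$cancer_type == "CT1", .data$restricted)
  recall <- mean(planted %in% rec$gene_id)
  expect_gte(recall, 0.9)
})

test_that("pca_distance_ratio flags degenerate input and separates planted types", {
  # two types at two distinct points, zero within-type spread
  expr <- matrix(c(10, 10, 0, 0,
                   0, 0, 10, 10), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  types <- stats::setNames(c("A", "A", "B", "B"), colnames(expr))
  expect_equal(pca_distance_ratio(expr, types, c("g1", "g2")), Inf)
  expect_error(pca_distance_ratio(expr * 0, types, c("g1", "g2")),
               "degenerate")

  set.seed(15)
  ng <- 40; ns <- 30
  expr <- matrix(2^stats::rnorm(ng * ns, 5, 1), nrow = ng,
                 dimnames = list(sprintf("g%02d", 1:ng),
                                 sprintf("s%02d", 1:ns)))
  types <- stats::setNames(rep(c("A", "B", "C"), each = 10), colnames(expr))
  # permuted labels: no structure, ratio near 1
  ratios <- replicate(100, {
    pca_distance_ratio(expr, stats::setNames(sample(types), names(types)),
                       rownames(expr))
  })
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
  # planted type effect pushes the ratio up
  expr2 <- expr
  expr2[1:20, types == "A"] <- expr2[1:20, types == "A"] * 8
  expect_gt(pca_distance_ratio(expr2, types, rownames(expr)), 1.5)
})

test_that("signature_score averages log2(FPKM + 1) per sample", {
  expr <- matrix(c(3, 1,
                   15, 7), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_equal(signature_score(expr, "gA"), log2(expr["gA", ] + 1))
  expect_equal(signature_score(expr, c("gA", "gB")),
               c(s1 = mean(c(2, 4)), s2 = mean(c(1, 3))))
  expect_warning(sc <- signature_score(expr, c("gA", "missing")), "absent")
  expect_equal(sc, log2(expr["gA", ] + 1))
  expect_error(signature_score(expr, "nope"), "no signature gene")
})

test_that("bundled CD8 signatures load from extdata", {
  sig <- cd8_signatures()
  expect_named(sig, c("CD8_SIGNATURE_A", "CD8_SIGNATURE_B"))
  expect_equal(length(sig$CD8_SIGNATURE_A), 12)
  expect_setequal(sig$CD8_SIGNATURE_B, c("GZMA", "PRF1"))
})

test_that("stratified_group_test is a one-sided Welch test on quantile strata", {
  df <- tibble::tibble(strat = 1:20, outcome = rep(1:4, 5))
  # identical outcome distributions in both strata -> t = 0, p = 0.5
  df$outcome <- rep(c(1, 2, 3, 4), each = 5)[order(order(df$strat))]
  df2 <- tibble::tibble(strat = 1:20,
                        outcome = c(1, 2, 3, 4, rep(0, 12), 1, 2, 3, 4))
  out <- stratified_group_test(df2, "strat", "outcome", quantile = 0.2)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 0.5)
  # a large shift in the top stratum is detected
  df3 <- tibble::tibble(strat = 1:40,
                        outcome = c(stats::rnorm(32), stats::rnorm(8, 50)))
  out <- stratified_group_test(df3, "strat", "outcome", quantile = 0.2)
  expect_lt(out$p, 1e-6)
  expect_error(stratified_group_test(df3[1:3, ], "strat", "outcome", 0.2),
               "strata")
})

test_that("rejection rate matches analytic Welch power at d = 1, n = 30/30", {
  set.seed(16)
  n <- 30; d <- 1
  rejections <- replicate(400, {
    df <- tibble::tibble(strat = c(rep(0, n), rep(1, n)),
                         outcome = c(stats::rnorm(n), stats::rnorm(n, d)))
    stratified_group_test(df, "strat", "outcome", quantile = 0.5)$p < 0.05
  })
  dfree <- 2 * n - 2
  power <- 1 - stats::pt(stats::qt(0.95, dfree), dfree, ncp = d * sqrt(n / 2))
  expect_equal(mean(rejections), power, tolerance = 0.05)
})

test_that("TF-stratified target fold changes categorize coupled targets", {
  set.seed(17)
  ns <- 50
  tf <- 2^stats::rnorm(ns, 5, 1)
  expr <- rbind(TF = tf, target = tf * 2, flat = rep(8, ns))
  colnames(expr) <- sprintf("s%02d", 1:ns)
  out <- tf_stratified_target_fc(expr, "TF", c("target", "flat"))
  expect_equal(out$category[out$gene_id == "target"], "up")
  expect_equal(out$category[out$gene_id == "flat"], "unchanged")
  expect_error(tf_stratified_target_fc(expr[, 1:5], "TF", "target"),
               "quantile|quintile|samples")
  expect_error(tf_stratified_target_fc(expr, "absent", "target"), "absent")
})

test_that("simulated TF-target coupling is recovered from the cohort", {
  s <- default_sim()
  res <- default_run()
  tf <- s$ann$tf_genes[["active"]]
  targets <- s$ann$tf_targets$active
  samples <- s$coh$samples
  ct1_tumors <- samples$sample_id[samples$cancer_type == "CT1" &
                                    samples$condition == "tumor"]
  out <- tf_stratified_target_fc(res$fpkm[, ct1_tumors], tf, targets)
  expect_gte(mean(out$category == "up"), 0.8)
})
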