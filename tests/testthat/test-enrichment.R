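test_that("binomial z statistic matches an independent plug-in evaluation", {
  fg <- sprintf("f%03d", 1:100)
  bg <- sprintf("b%03d", 1:100)
  set <- c(fg[1:20], bg[1:10]) # k/n = 0.2, raw bg rate 0.1
  out <- binomial_z_enrichment(fg, bg, list(S = set))
  row <- out[out$direction == "fg_vs_bg", ]
  p0 <- (10 + 0.5) / (100 + 1)
  z <- (20 / 100 - p0) / sqrt(p0 * (1 - p0) / 100)
  expect_equal(row$p0, p0, tolerance = 1e-12)
  expect_equal(row$z, z, tolerance = 1e-10)
  expect_equal(row$p, stats::pnorm(z, lower.tail = FALSE), tolerance = 1e-10)
  # k/n equal to p0 gives z = 0, p = 0.5
  p0r <- (10 + 0.5) / 101
  k0 <- round(p0r * 100)
  set2 <- c(fg[seq_len(k0)], bg[1:10])
  row2 <- binomial_z_enrichment(fg, bg, list(S = set2))
  row2 <- row2[row2$direction == "fg_vs_bg", ]
  expect_equal(row2$z, (k0 / 100 - p0r) / sqrt(p0r * (1 - p0r) / 100),
               tolerance = 1e-12)
})

test_that("binomial z p is monotone in k and reciprocal directions oppose", {
  fg <- sprintf("f%03d", 1:100)
  bg <- sprintf("b%03d", 1:100)
  ps <- vapply(c(5, 10, 20, 40), function(k) {
    out <- binomial_z_enrichment(fg, bg, list(S = c(fg[seq_len(k)], bg[1:10])))
    out$p[out$direction == "fg_vs_bg"]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  out <- binomial_z_enrichment(fg, bg, list(S = c(fg[1:40], bg[1:5])))
  expect_true(out$z[out$direction == "fg_vs_bg"] > 0)
  expect_true(out$z[out$direction == "bg_vs_fg"] < 0)
  expect_error(binomial_z_enrichment(fg, fg, list(S = fg)), "disjoint")
  expect_message(binomial_z_enrichment(fg, bg, list(S = fg[1:3],
                                                    E = character(0))),
                 "empty")
})

test_that("planted gene sets are detected in the correct direction only", {
  res <- default_run()
  enr <- res$set_enrichment
  emt <- enr[enr$set_id == "SET_EMT_LIKE", ]
  expect_true(emt$enriched[emt$direction == "fg_vs_bg"])
  expect_false(emt$enriched[emt$direction == "bg_vs_fg"])
  cc <- enr[enr$set_id == "SET_CELL_CYCLE_LIKE", ]
  expect_true(cc$enriched[cc$direction == "bg_vs_fg"])
  expect_false(cc$enriched[cc$direction == "fg_vs_bg"])
})

test_that("hypergeometric enrichment matches exact enumeration (N <= 30 grid)", {
  for (N in c(6, 10, 17, 25, 30)) {
    for (n in unique(c(2, N %/% 3, N %/% 2, N - 2))) {
      for (K in unique(c(0, 1, N %/% 4, N %/% 2, N))) {
        for (k in unique(c(max(0, K - (N - n)), min(1, K), min(n, K)))) {
          if (k > n || K - k > N - n) next
          fg <- regions_with_motif(n, k)
          bg <- regions_with_motif(N - n, K - k, offset = n + 100)
          out <- hypergeom_region_enrichment(
            fg$regions, bg$regions,
            list(TF = dplyr::bind_rows(fg$occ, bg$occ)),
            c(TF = 50)
          )
          expect_equal(out$p, oracle_hyper_upper(k, N, K, n),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric example and edge cases behave", {
  fg <- regions_with_motif(10, 4)
  bg <- regions_with_motif(40, 4, offset = 200)
  out <- hypergeom_region_enrichment(fg$regions, bg$regions,
                                     list(TF = dplyr::bind_rows(fg$occ, bg$occ)),
                                     c(TF = 50))
  expect_equal(out$p, oracle_hyper_upper(4, 50, 8, 10), tolerance = 1e-12)
  expect_equal(out$k_fg, 4)
  # motif in every region: no enrichment signal, p = 1
  fg <- regions_with_motif(10, 10)
  bg <- regions_with_motif(20, 20, offset = 200)
  out <- hypergeom_region_enrichment(fg$regions, bg$regions,
                                     list(TF = dplyr::bind_rows(fg$occ, bg$occ)),
                                     c(TF = 50))
  expect_equal(out$p, 1, tolerance = 1e-12)
})

test_that("the TF expression gate and missing-TF warning apply", {
  fg <- regions_with_motif(10, 8)
  bg <- regions_with_motif(40, 4, offset = 200)
  motifs <- list(TFhi = dplyr::bind_rows(fg$occ, bg$occ),
                 TFlo = dplyr::bind_rows(fg$occ, bg$occ))
  out <- hypergeom_region_enrichment(fg$regions, bg$regions, motifs,
                                     c(TFhi = 50, TFlo = 2))
  expect_true(out$enriched[out$tf == "TFhi"])
  expect_false(out$enriched[out$tf == "TFlo"]) # significant but not expressed
  expect_lt(out$p[out$tf == "TFlo"], 0.01)
  expect_warning(
    out2 <- hypergeom_region_enrichment(fg$regions, bg$regions, motifs,
                                        c(TFhi = 50)),
    "excluded"
  )
  expect_equal(out2$tf, "TFhi")
})

test_that("the planted motif is enriched in the cohort's foreground enhancers", {
  res <- default_run()
  s <- default_sim()
  enr <- res$motif_enrichment
  active <- s$ann$tf_genes[["active"]]
  nulltf <- s$ann$tf_genes[["null"]]
  lowtf <- s$ann$tf_genes[["lowexpr"]]
  expect_true(enr$enriched[enr$tf == active])
  expect_false(enr$enriched[enr$tf == nulltf])
  expect_false(enr$enriched[enr$tf == lowtf]) # gated by expression
  expect_false(enr$expressed[enr$tf == lowtf])
})

test_that("Fisher test matches enumeration and its invariances", {
  m <- matrix(c(3, 7, 1, 9), nrow = 2, byrow = TRUE)
  out <- fisher_overlap_test(m)
  expect_equal(out$p, oracle_fisher_two_sided(m), tolerance = 1e-12)
  set.seed(19)
  for (rep in 1:30) {
    m <- matrix(sample(0:12, 4, replace = TRUE), nrow = 2)
    if (sum(m) == 0) next
    out <- fisher_overlap_test(m)
    expect_equal(out$p, oracle_fisher_two_sided(m), tolerance = 1e-9)
    expect_equal(out$p, fisher_overlap_test(t(m))$p, tolerance = 1e-12)
  }
  expect_equal(fisher_overlap_test(matrix(5, 2, 2))$p, 1)
  expect_lt(fisher_overlap_test(matrix(c(10, 0, 0, 10), 2))$p, 1e-4)
  # Haldane-corrected sample odds ratio on a zero cell
  out <- fisher_overlap_test(matrix(c(4, 0, 2, 6), nrow = 2, byrow = TRUE))
  expect_equal(out$odds_ratio, (4.5 * 6.5) / (0.5 * 2.5))
  expect_error(fisher_overlap_test(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("enhancers per gene count distinct peaks and zero-link genes", {
  links <- tibble::tibble(
    peak_id = c("e1", "e2", "e3", "e3"),
    gene_id = c("g1", "g1", "g1", "g2"),
    chrom = "chr1", start = c(1, 100, 200, 200), end = c(50, 150, 250, 250)
  )
  out <- enhancers_per_gene(links, list(A = c("g1", "g2"), B = "g_absent"))
  expect_equal(out$mean_links[out$class == "A"], 2) # (3 + 1) / 2
  expect_equal(out$mean_links[out$class == "B"], 0)
  regions <- linked_regions_for_genes(links, c("g1", "g2"))
  expect_equal(nrow(regions), 3) # shared enhancer counted once
  expect_equal(nrow(linked_regions_for_genes(links, "g2")), 1)
})

test_that("simulated enhancer-link means recover the Poisson parameters", {
  res <- default_run()
  e <- res$enhancers
  expect_equal(e$mean_links[e$class == "PRC2_POS"], 2.9, tolerance = 0.2 / 2.9)
  expect_equal(e$mean_links[e$class == "PRC2_NEG"], 1.9, tolerance = 0.2 / 1.9)
  expect_gt(e$mean_links[e$class == "PRC2_POS"],
            e$mean_links[e$class == "PRC2_NEG"])
})

test_that("GMT files round-trip", {
  sets <- list(A = c("g1", "g2"), B = c("g3"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back, sets)
})
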