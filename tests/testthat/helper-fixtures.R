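# Shared fixtures, built in code and memoised per test session.

memo <- function(fn) {
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fn()
    cache
  }
}

# reference study conditions: 3 cancer types, 2,000 genes, 40 tumors and 10
# normals per type, seed 1
default_sim <- memo(function() {
  cfg <- sim_config(seed = 1)
  ann <- simulate_annotation(cfg)
  coh <- simulate_cohort(cfg, ann)
  list(cfg = cfg, ann = ann, coh = coh)
})

default_run <- memo(function() {
  suppressWarnings(run_pipeline(pipeline_config(seed = 1)))
})

# reduced cohort for module-level tests
small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_genes = 300, n_cancer_types = 2, n_normal = 8,
             n_tumor = 20, ...)
}

small_sim <- memo(function() {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  coh <- simulate_cohort(cfg, ann)
  list(cfg = cfg, ann = ann, coh = coh)
})

small_run <- memo(function() {
  suppressWarnings(run_pipeline(pipeline_config(seed = 11,
                                                simulate = small_cfg())))
})

# --- independent brute-force oracles (kept naive on purpose) ---------------

# per-base membership oracle for interval overlap on one small chromosome
oracle_overlap <- function(queries, subjects, chrom_len = 10000) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(subjects))) {
    if (subjects$end[i] > subjects$start[i]) {
      covered[(subjects$start[i] + 1):subjects$end[i]] <- TRUE
    }
  }
  vapply(seq_len(nrow(queries)), function(i) {
    any(covered[(queries$start[i] + 1):queries$end[i]])
  }, logical(1))
}

# per-base signal oracle: value vector indexed by 0-based position + 1
oracle_signal_vector <- function(track, chrom_len = 10000) {
  v <- numeric(chrom_len)
  for (i in seq_len(nrow(track))) {
    v[(track$start[i] + 1):track$end[i]] <- track$value[i]
  }
  v
}

oracle_mean_signal <- function(track, start, end, chrom_len = 10000) {
  v <- oracle_signal_vector(track, chrom_len)
  mean(v[(start + 1):end])
}

# BH step-up oracle, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

# exact upper-tail hypergeometric by enumeration over the support
oracle_hyper_upper <- function(k, N, K, n) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  if (k > hi) return(0)
  kk <- max(k, lo):hi
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# two-sided Fisher by enumeration over tables with fixed margins
oracle_fisher_two_sided <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- sum(m)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  }, numeric(1))
  obs <- probs[m[1, 1] - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# n regions of which the first k carry one motif occurrence each
regions_with_motif <- function(n, k, offset = 0) {
  start <- (offset + seq_len(n)) * 1000
  reg <- tibble::tibble(chrom = "chrT", start = start, end = start + 200)
  occ <- tibble::tibble(chrom = "chrT", start = start[seq_len(k)] + 50,
                        end = start[seq_len(k)] + 60)
  list(regions = reg, occ = occ)
}

# random interval set on a toy chromosome
random_intervals <- function(n, chrom_len = 10000, max_len = 400) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = "chrT", start = start, end = start + len)
}
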