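# Class-level chromatin summaries: LAD fractions, TSS-centered signal
# profiles and feature/class correlations.

#' Fraction of promoters overlapping LADs, per class
#'
#' @param promoters_by_class Named list of interval tibbles (one per gene
#'   class).
#' @param lad_bed LAD intervals.
#' @return Tibble `class`, `n`, `lad_fraction` (`NA` for an empty class,
#'   reported with a warning).
#' @export
lad_fraction_by_class <- function(promoters_by_class, lad_bed) {
  purrr::imap_dfr(promoters_by_class, function(pr, cls) {
    if (is.null(pr) || nrow(pr) == 0) {
      warn(sprintf("class %s is empty; LAD fraction reported as missing", cls))
      return(tibble(class = cls, n = 0L, lad_fraction = NA_real_))
    }
    tibble(class = cls, n = nrow(pr),
           lad_fraction = fraction_overlapping(pr, lad_bed))
  })
}

#' TSS-centered, strand-oriented signal profile
#'
#' Bins of `bin_bp` tile the window from `-flank_bp` to `+flank_bp` around
#' each TSS. Minus-strand promoters are mirrored so that bin 1 is always the
#' most upstream bin. Uncovered bases contribute 0 signal.
#'
#' @param track Signal track tibble (see [read_bedgraph()]).
#' @param promoters Tibble with columns `chrom`, `tss` (0-based TSS base),
#'   `strand` and an id column `promoter_id`; an optional `class` column is
#'   carried into the per-class mean curves.
#' @param flank_bp Half-window size (default 2000); must be divisible by
#'   `bin_bp`.
#' @param bin_bp Bin width (default 100).
#' @return List of class `cgip_profile`: `matrix` (promoters x bins),
#'   `bin_mid` (bin midpoints relative to the TSS), `promoter_mean`
#'   (per-promoter mean for heatmap ordering), `class_mean` (tibble, present
#'   when `promoters$class` exists).
#' @export
tss_signal_profile <- function(track, promoters, flank_bp = 2000,
                               bin_bp = 100) {
  if (flank_bp %% bin_bp != 0) abort("flank_bp must be divisible by bin_bp")
  track <- validate_track(track)
  need <- setdiff(c("chrom", "tss", "strand", "promoter_id"), names(promoters))
  if (length(need) > 0) {
    abort(paste0("`promoters` lacks column(s): ", paste(need, collapse = ", ")))
  }
  nb <- 2L * flank_bp %/% bin_bp
  np <- nrow(promoters)
  offs <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  # one row per promoter x bin, in genomic orientation
  grid <- tidyr::expand_grid(i = seq_len(np), off = offs) |>
    mutate(chrom = promoters$chrom[.data$i],
           start = pmax(0L, as.integer(promoters$tss[.data$i] + .data$off)),
           end = as.integer(promoters$tss[.data$i] + .data$off + bin_bp))
  vals <- mean_signal_in_window(track, grid)
  m <- matrix(vals, nrow = np, ncol = nb, byrow = TRUE,
              dimnames = list(promoters$promoter_id, NULL))
  minus <- promoters$strand == "-"
  m[minus, ] <- m[minus, nb:1, drop = FALSE]
  bin_mid <- offs + bin_bp / 2
  colnames(m) <- sprintf("bin_%+05d", as.integer(bin_mid))
  out <- list(matrix = m, bin_mid = bin_mid, promoter_mean = rowMeans(m))
  if ("class" %in% names(promoters)) {
    out$class_mean <- tibble(class = rep(promoters$class, nb),
                             bin_mid = rep(bin_mid, each = np),
                             value = as.vector(m)) |>
      group_by(.data$class, .data$bin_mid) |>
      summarise(value = mean(.data$value), .groups = "drop")
  }
  class(out) <- "cgip_profile"
  out
}

#' Centered moving-window trend
#'
#' Rolling mean of a fixed window; near the edges the window is shifted (not
#' shrunk) so it always covers `window` positions where the vector allows.
#'
#' @param values Numeric vector, already sorted by the ordering signal.
#' @param window Window size in positions (default 100).
#' @return Smoothed numeric vector of the same length.
#' @export
moving_window_trend <- function(values, window = 100) {
  n <- length(values)
  if (window < 1) abort("window must be >= 1")
  if (window > n) abort("window larger than the vector")
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  starts <- pmax(1L, pmin(seq_len(n) - h, n - window + 1L))
  (cs[starts + window] - cs[starts]) / window
}

#' Pearson correlation between class membership and promoter features
#'
#' @param class_membership Logical or 0/1 vector per promoter.
#' @param features Data frame or matrix of per-promoter feature values.
#' @return Tibble `feature`, `r` (`NA` with a warning for zero-variance
#'   features).
#' @export
feature_class_correlation <- function(class_membership, features) {
  y <- as.numeric(class_membership)
  if (length(y) < 3) abort("need at least 3 promoters")
  if (stats::sd(y) == 0) abort("class membership is constant")
  features <- as.data.frame(features)
  purrr::imap_dfr(features, function(f, nm) {
    if (stats::sd(f) == 0) {
      warn(sprintf("feature %s has zero variance; correlation missing", nm))
      return(tibble(feature = nm, r = NA_real_))
    }
    tibble(feature = nm, r = stats::cor(y, f))
  })
}
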