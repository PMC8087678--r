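#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n distinct pull across rename if_else row_number
#' @importFrom tibble tibble as_tibble
#' @import ggplot2
NULL

# Internal coordinate convention: 0-based, half-open [start, end), like BED.
# Strand is one of "+", "-", "." and is ignored by all overlap tests.

VALID_STRANDS <- c("+", "-", ".")

#' Validate a genomic-interval tibble
#'
#' Interval tables are plain tibbles with columns `chrom`, `start`, `end` and
#' optionally `strand` and `name`. Coordinates are 0-based half-open, the BED
#' convention. Missing `strand`/`name` columns are filled with `"."`/`NA`.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`.
#' @export
as_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` lacks interval column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"strand" %in% names(x)) x$strand <- "."
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (nrow(x) > 0) {
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad) > 0) {
      abort(sprintf("`%s` row %d violates 0 <= start < end (start=%s, end=%s)",
                    arg, bad[1], x$start[bad[1]], x$end[bad[1]]))
    }
    if (any(!x$strand %in% VALID_STRANDS)) {
      abort(sprintf("`%s` has strand values outside {+, -, .}", arg))
    }
  }
  x
}

# 0-based half-open tibble -> GRanges (1-based closed). Strand dropped on
# purpose: every overlap test in the pipeline is strand-blind.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Read a BED3/BED6 file
#'
#' Tab-separated; `track`, `browser` and `#` lines are skipped. Coordinates are
#' taken verbatim (BED is already 0-based half-open). Strand is `"."` when
#' column 6 is absent.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("BED parse error at line %d: fewer than 3 fields", i))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("BED parse error at line %d: non-integer coordinates", i))
    }
    if (start < 0 || start >= end) {
      abort(sprintf("BED parse error at line %d: start >= end or negative", i))
    }
    strand <- if (length(f) >= 6) f[6] else "."
    if (!strand %in% VALID_STRANDS) {
      abort(sprintf("BED parse error at line %d: bad strand '%s'", i, strand))
    }
    j <- j + 1L
    out[[j]] <- tibble(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_,
      strand = strand
    )
  }
  if (j == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  bind_rows(out[seq_len(j)])
}

#' Write intervals as BED6
#'
#' @param x Interval tibble (see [as_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  score <- if ("score" %in% names(x)) x$score else NA_real_
  lines <- paste(x$chrom, x$start, x$end,
                 if_else(is.na(x$name), ".", x$name),
                 if_else(is.na(score), 0, score),
                 x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Plain 4-column text (chrom, start, end, value). Intervals must be
#' non-overlapping within a chromosome; the result is sorted. Bases not
#' covered by any record are read as signal 0 throughout the package.
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(sprintf("bedGraph file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) abort("bedGraph parse error: fewer than 4 fields")
  tr <- tibble(
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 2)),
    end = as.integer(vapply(f, `[`, character(1), 3)),
    value = as.numeric(vapply(f, `[`, character(1), 4))
  )
  validate_track(tr)
}

validate_track <- function(track) {
  track <- as_intervals(track, "track")
  if (!"value" %in% names(track)) abort("signal track needs a `value` column")
  track <- arrange(track, .data$chrom, .data$start)
  ok <- track |>
    group_by(.data$chrom) |>
    summarise(ok = all(.data$start[-1] >= .data$end[-n()]) || n() <= 1) |>
    pull(.data$ok)
  if (!all(ok)) abort("signal track has overlapping intervals within a chromosome")
  select(track, "chrom", "start", "end", "value")
}

#' Strand-aware promoter window around a TSS
#'
#' Builds the promoter interval spanning `upstream` bp upstream to
#' `downstream` bp downstream of each TSS, inclusive of the TSS base
#' (length `upstream + downstream + 1` unless clipped at position 0).
#' On the plus strand this is `[tss - upstream, tss + downstream + 1)`;
#' minus-strand windows are mirrored.
#'
#' @param tss Data frame with columns `chrom`, `position` (0-based TSS base)
#'   and `strand` (`"+"` or `"-"`; `"."` is an error since promoters require
#'   orientation). Extra columns are carried through.
#' @param upstream,downstream Window extent in bp (defaults 250 and 500).
#' @return Tibble of promoter intervals with the original columns plus
#'   `start`, `end`.
#' @export
promoter_window <- function(tss, upstream = 250, downstream = 500) {
  if (!is.data.frame(tss)) abort("`tss` must be a data frame")
  tss <- as_tibble(tss)
  need <- setdiff(c("chrom", "position", "strand"), names(tss))
  if (length(need) > 0) {
    abort(paste0("`tss` lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (any(tss$position < 0)) abort("TSS positions must be >= 0")
  if (any(!tss$strand %in% c("+", "-"))) {
    abort("promoter windows require strand '+' or '-'")
  }
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$position - upstream, tss$position - downstream)
  end <- ifelse(plus, tss$position + downstream + 1, tss$position + upstream + 1)
  tss$start <- as.integer(pmax(0, start))
  tss$end <- as.integer(end)
  tss
}

#' Flag queries overlapping any subject by at least 1 bp
#'
#' Half-open semantics: `[10,20)` and `[20,25)` do not overlap. Strand is
#' ignored; only same-chromosome overlap counts.
#'
#' @param queries,subjects Interval tibbles.
#' @return Logical vector, one flag per query row.
#' @export
overlap_any <- function(queries, subjects) {
  queries <- as_intervals(queries, "queries")
  subjects <- as_intervals(subjects, "subjects")
  if (nrow(queries) == 0) return(logical(0))
  if (nrow(subjects) == 0) return(rep(FALSE, nrow(queries)))
  # disjoint chromosome sets between queries and subjects are a legitimate
  # no-overlap situation, not worth a seqlevel warning
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(queries), as_granges0(subjects),
                                 minoverlap = 1L)
  )
  hits > 0
}

#' Proportion of queries overlapping any subject
#'
#' @inheritParams overlap_any
#' @return A proportion in `[0, 1]`.
#' @export
fraction_overlapping <- function(queries, subjects) {
  queries <- as_intervals(queries, "queries")
  if (nrow(queries) == 0) abort("`queries` must be non-empty")
  mean(overlap_any(queries, subjects))
}

#' Length-weighted mean signal over intervals
#'
#' Mean signal per base over each query window; bases not covered by the
#' track contribute 0.
#'
#' @param track Signal track tibble (`chrom`, `start`, `end`, `value`),
#'   e.g. from [read_bedgraph()].
#' @param intervals Interval tibble of query windows.
#' @return Numeric vector of per-window means.
#' @export
mean_signal_in_window <- function(track, intervals) {
  track <- validate_track(track)
  intervals <- as_intervals(intervals, "intervals")
  if (nrow(intervals) == 0) return(numeric(0))
  if (nrow(track) == 0) return(rep(0, nrow(intervals)))
  hits <- GenomicRanges::findOverlaps(as_granges0(intervals), as_granges0(track))
  out <- rep(0, nrow(intervals))
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(intervals$end[qi], track$end[si]) -
      pmax(intervals$start[qi], track$start[si])
    contrib <- tapply(ov * track$value[si], qi, sum)
    out[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  out / (intervals$end - intervals$start)
}
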