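# Downstream read- and peak-level operations. Coordinates follow the BED
# convention throughout: 0-based starts, half-open [start, end) intervals.

#' Remove potential PCR duplicates
#'
#' Keeps at most one read per (chrom, start, strand) triple, preserving the
#' first occurrence. Idempotent.
#'
#' @param reads Tibble with columns `chrom`, `start`, `strand`.
#' @return Deduplicated tibble.
#' @export
dedup_reads <- function(reads) {
  reads <- as_tibble(reads)
  assert_columns(reads, c("chrom", "start", "strand"), "`reads`")
  dplyr::distinct(reads, .data$chrom, .data$start, .data$strand, .keep_all = TRUE)
}

#' Subsample read sets to equal depth
#'
#' Draws `min(sizes)` reads uniformly without replacement from every sample
#' (including IgG and knockdown controls) so all sets have equal depth.
#'
#' @param read_sets Named list of read tibbles; all non-empty.
#' @param seed Integer seed for reproducible draws.
#' @return Named list of read tibbles, each with exactly `min(sizes)` rows.
#' @export
subsample_equal <- function(read_sets, seed = NULL) {
  stopifnot(is.list(read_sets), length(read_sets) >= 1)
  sizes <- vapply(read_sets, nrow, integer(1))
  if (any(sizes == 0)) {
    rlang::abort(sprintf("empty read set(s): %s",
                         paste(names(read_sets)[sizes == 0], collapse = ", ")))
  }
  target <- min(sizes)
  with_seed(seed, {
    purrr::map(read_sets, function(r) {
      r[sort(sample.int(nrow(r), target)), , drop = FALSE]
    })
  })
}

#' Filter peaks by fold enrichment over IgG
#'
#' Retains peaks whose `fold_enrichment` is at least `min_fold` (inclusive
#' boundary, matching "at least 100-fold"); input order is preserved.
#'
#' @param peaks Peak tibble with a `fold_enrichment` column.
#' @param min_fold Minimum fold enrichment; default 100.
#' @return Filtered peak tibble.
#' @export
filter_peaks <- function(peaks, min_fold = 100) {
  peaks <- as_tibble(peaks)
  if (!"fold_enrichment" %in% names(peaks)) {
    rlang::abort("`peaks` has no `fold_enrichment` column")
  }
  dplyr::filter(peaks, .data$fold_enrichment >= min_fold)
}

#' Peak count and mean width
#'
#' @param peaks Peak tibble with `start`, `end` (half-open).
#' @return One-row tibble with `n_peaks` and `mean_width` (bp).
#' @export
peak_stats <- function(peaks) {
  peaks <- as_tibble(peaks)
  assert_columns(peaks, c("start", "end"), "`peaks`")
  tibble(n_peaks = nrow(peaks),
         mean_width = mean(peaks$end - peaks$start))
}

#' Per-peak read density (reads per kb)
#'
#' Counts reads whose start falls in `[start, end)` of each peak and divides
#' by the peak width in kb. Intended for deduplicated, depth-matched reads.
#' Counting uses binary search on per-chromosome sorted read starts.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param reads Read tibble (`chrom`, `start`).
#' @return `peaks` with `n_reads` and `density` (reads/kb) columns added.
#' @export
read_density <- function(peaks, reads) {
  peaks <- as_tibble(peaks)
  reads <- as_tibble(reads)
  assert_columns(peaks, c("chrom", "start", "end"), "`peaks`")
  assert_columns(reads, c("chrom", "start"), "`reads`")
  starts_by_chrom <- split(reads$start, reads$chrom)
  starts_by_chrom <- lapply(starts_by_chrom, sort)
  count_in <- function(chrom, s, e) {
    rs <- starts_by_chrom[[chrom]]
    if (is.null(rs)) return(0L)
    # reads with start in [s, e): rank of e-1 minus rank of s-1
    findInterval(e - 1L, rs) - findInterval(s - 1L, rs)
  }
  n <- purrr::pmap_int(list(peaks$chrom, peaks$start, peaks$end), count_in)
  dplyr::mutate(peaks, n_reads = n,
                density = n / ((.data$end - .data$start) / 1000))
}

#' Distance from each query summit to the nearest summit of another factor
#'
#' For every peak summit in `query`, the minimum absolute distance to any
#' summit in `other` on the same chromosome; `NA` when the chromosome is
#' absent from `other`.
#'
#' @param query,other Peak tibbles with `chrom` and `summit` columns.
#' @return `query` with a `nearest_distance` column added.
#' @export
nearest_factor_distance <- function(query, other) {
  query <- as_tibble(query)
  other <- as_tibble(other)
  assert_columns(query, c("chrom", "summit"), "`query`")
  assert_columns(other, c("chrom", "summit"), "`other`")
  if (nrow(query) == 0 || nrow(other) == 0) {
    rlang::abort("both peak sets must be non-empty")
  }
  by_chrom <- lapply(split(other$summit, other$chrom), sort)
  nearest_one <- function(chrom, s) {
    os <- by_chrom[[chrom]]
    if (is.null(os)) return(NA_real_)
    i <- findInterval(s, os)
    cand <- c(if (i >= 1) os[i], if (i < length(os)) os[i + 1])
    min(abs(cand - s))
  }
  dplyr::mutate(query,
                nearest_distance = purrr::map2_dbl(.data$chrom, .data$summit,
                                                   nearest_one))
}
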