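# Plain-text readers/writers. BED files are 0-based, half-open; violations
# are hard errors naming the file, line and rule — never silently clamped.

read_tsv_quiet <- function(path, col_names, col_types) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, col_names = col_names, col_types = col_types,
                  progress = FALSE)
}

bed_check <- function(df, path, need_strand = FALSE) {
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s line %d: start must be a non-negative number",
                         path, bad[1]))
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s line %d: violates start < end (half-open BED)",
                         path, bad[1]))
  }
  if (need_strand) {
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad) > 0) {
      rlang::abort(sprintf("%s line %d: strand must be '+' or '-'", path, bad[1]))
    }
  }
  invisible(df)
}

#' Read and write aligned read positions as BED
#'
#' Reads are stored as BED6 (`chrom`, `start`, `end`, `name`, `score`,
#' `strand`); only chrom, 0-based start and strand are semantic. On write,
#' `end = start + read_length`.
#'
#' @param path File path.
#' @return `read_reads_bed()`: tibble with `chrom`, `start`, `strand`.
#' @export
read_reads_bed <- function(path) {
  df <- read_tsv_quiet(path,
                       col_names = c("chrom", "start", "end", "name", "score", "strand"),
                       col_types = "ciicdc")
  bed_check(df, path, need_strand = TRUE)
  dplyr::select(df, "chrom", "start", "strand")
}

#' @rdname read_reads_bed
#' @param reads Read tibble (`chrom`, `start`, `strand`).
#' @param read_length Read length used for the BED `end` column; default 36.
#' @export
write_reads_bed <- function(reads, path, read_length = 36) {
  assert_columns(reads, c("chrom", "start", "strand"), "`reads`")
  out <- tibble(chrom = reads$chrom, start = as.integer(reads$start),
                end = as.integer(reads$start) + as.integer(read_length),
                name = ".", score = 0, strand = reads$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write peak calls as BED6+2
#'
#' Columns 1-6 are standard BED; column 7 is the summit offset from `start`
#' and column 8 the fold enrichment over IgG.
#'
#' @param path File path.
#' @return `read_peaks_bed()`: tibble with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit` (absolute bp), `fold_enrichment`.
#' @export
read_peaks_bed <- function(path) {
  df <- read_tsv_quiet(path,
                       col_names = c("chrom", "start", "end", "name", "score",
                                     "strand", "summit_offset", "fold_enrichment"),
                       col_types = "ciicdcid")
  bed_check(df, path)
  bad <- which(df$summit_offset < 0 | df$summit_offset >= df$end - df$start)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s line %d: summit offset outside the peak interval",
                         path, bad[1]))
  }
  bad <- which(df$fold_enrichment < 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s line %d: fold_enrichment must be >= 0", path, bad[1]))
  }
  df |>
    dplyr::mutate(summit = .data$start + .data$summit_offset) |>
    dplyr::select("chrom", "start", "end", "name", "score", "strand",
                  "summit", "fold_enrichment")
}

#' @rdname read_peaks_bed
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `summit`,
#'   `fold_enrichment` (and optionally `name`, `score`, `strand`).
#' @export
write_peaks_bed <- function(peaks, path) {
  assert_columns(peaks, c("chrom", "start", "end", "summit", "fold_enrichment"),
                 "`peaks`")
  out <- tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = if ("name" %in% names(peaks)) peaks$name else ".",
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else ".",
    summit_offset = as.integer(peaks$summit - peaks$start),
    fold_enrichment = peaks$fold_enrichment
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write gene models as BED6
#'
#' The BED name column carries the gene id; the TSS is derived from the
#' strand (start on `+`, end - 1 on `-`).
#'
#' @param path File path.
#' @return `read_genes_bed()`: tibble with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`.
#' @export
read_genes_bed <- function(path) {
  df <- read_tsv_quiet(path,
                       col_names = c("chrom", "start", "end", "name", "score", "strand"),
                       col_types = "ciicdc")
  bed_check(df, path, need_strand = TRUE)
  df |>
    dplyr::transmute(gene_id = .data$name, chrom = .data$chrom,
                     start = .data$start, end = .data$end,
                     strand = .data$strand,
                     tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))
}

#' @rdname read_genes_bed
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
write_genes_bed <- function(genes, path) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "`genes`")
  out <- tibble(chrom = genes$chrom, start = as.integer(genes$start),
                end = as.integer(genes$end), name = genes$gene_id,
                score = 0, strand = genes$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write grayscale channel images
#'
#' Channels are stored as 16-bit grayscale TIFF (or PNG, by file
#' extension). Intensities in arbitrary units are mapped onto the 16-bit
#' range \[0, 65535\]; values outside are an error, not clipped.
#'
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @return `read_image()`: numeric intensity matrix in \[0, 65535\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) > 2) img <- img[, , 1]
  img * 65535
}

#' @rdname read_image
#' @param image Numeric matrix with values in \[0, 65535\] (a.u.).
#' @export
write_image <- function(image, path) {
  if (any(image < 0) || any(image > 65535)) {
    rlang::abort("image intensities must lie in [0, 65535] for 16-bit storage")
  }
  type <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff"
  EBImage::writeImage(EBImage::Image(image / 65535), path, type = type,
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read and write screen plate tables as TSV
#'
#' Columns: `plate`, `well`, `replicate`, `sirna_id`, `gene_id`, `raw`
#' (header included). Control wells carry `sirna_id == "CONTROL"` and an
#' empty `gene_id`. On read, every (plate, replicate) must contain at least
#' one control well and raw values must be non-negative.
#'
#' @param path File path.
#' @return `read_screen_tsv()`: screen tibble.
#' @export
read_screen_tsv <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = "iciccd", progress = FALSE)
  assert_columns(df, c("plate", "well", "replicate", "sirna_id", "gene_id", "raw"),
                 sprintf("screen table %s", path))
  bad <- which(df$raw < 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s line %d: raw viability must be >= 0", path, bad[1] + 1))
  }
  no_ctrl <- df |>
    dplyr::summarise(has = any(.data$sirna_id == "CONTROL"),
                     .by = c("plate", "replicate")) |>
    dplyr::filter(!.data$has)
  if (nrow(no_ctrl) > 0) {
    rlang::abort(sprintf("%s: no CONTROL wells on plate %s replicate %s",
                         path, no_ctrl$plate[1], no_ctrl$replicate[1]))
  }
  df
}

#' @rdname read_screen_tsv
#' @param screen_tbl Screen tibble.
#' @export
write_screen_tsv <- function(screen_tbl, path) {
  assert_columns(screen_tbl,
                 c("plate", "well", "replicate", "sirna_id", "gene_id", "raw"),
                 "`screen_tbl`")
  readr::write_tsv(
    dplyr::select(screen_tbl, "plate", "well", "replicate", "sirna_id",
                  "gene_id", "raw"),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read and write ranked gene tables as TSV
#'
#' @param path File path.
#' @return `read_ranked_tsv()`: tibble with `rank`, `gene_id`, ordered.
#' @export
read_ranked_tsv <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = "ic", progress = FALSE)
  assert_columns(df, c("rank", "gene_id"), sprintf("ranked table %s", path))
  dplyr::arrange(df, .data$rank)
}

#' @rdname read_ranked_tsv
#' @param ranked Ranked tibble (`rank`, `gene_id`).
#' @export
write_ranked_tsv <- function(ranked, path) {
  assert_columns(ranked, c("rank", "gene_id"), "`ranked`")
  readr::write_tsv(dplyr::select(ranked, "rank", "gene_id"), path,
                   progress = FALSE)
  invisible(path)
}
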