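#' Segment nuclei and cells from DNA and whole-cell channels
#'
#' Nuclei are segmented from the DNA channel by a global Otsu threshold,
#' connected-component labelling and a minimum-area filter; cell bodies are
#' obtained by Voronoi-style propagation of the nucleus seeds over the
#' thresholded cell channel (watershed-like region growing, as in standard
#' CellProfiler-type pipelines). Cells touching the image border are
#' discarded (a truncated cytoplasm biases the ratio), as are cells without
#' a nucleus. Nucleus masks are clipped to their cell so each nucleus is
#' contained in exactly one cell mask.
#'
#' @param dna,cell Numeric intensity matrices of identical dimensions.
#' @param min_area Minimum nucleus area in px; smaller components are
#'   discarded. Default 20.
#' @param exclude_border Drop cells touching the image border; default TRUE.
#' @return A `cell_masks` list: `nuclei` and `cells` (integer label matrices
#'   sharing label ids) and `params` (threshold values and settings used).
#'   Zero cells yields empty masks with a warning.
#' @export
segment_cells <- function(dna, cell, min_area = 20, exclude_border = TRUE) {
  if (!all(dim(dna) == dim(cell))) rlang::abort("channel dimensions differ")
  rng <- range(dna)
  if (diff(rng) == 0) {
    rlang::warn("no nuclei found (flat DNA channel)")
    return(empty_masks(dim(dna), min_area, exclude_border))
  }
  scale01 <- function(m) (m - min(m)) / diff(range(m))
  dna01 <- scale01(dna)
  cell01 <- scale01(cell)
  thr_dna <- EBImage::otsu(EBImage::Image(dna01))
  thr_cell <- EBImage::otsu(EBImage::Image(cell01))
  nuc_bin <- dna01 > thr_dna
  if (!any(nuc_bin)) {
    rlang::warn("no nuclei found above threshold")
    return(empty_masks(dim(dna), min_area, exclude_border))
  }
  nuclei <- EBImage::bwlabel(EBImage::Image(nuc_bin))
  areas <- table(nuclei[nuclei > 0])
  small <- as.integer(names(areas)[areas < min_area])
  nuclei[nuclei %in% small] <- 0L
  if (!any(nuclei > 0)) {
    rlang::warn("no nuclei found after minimum-area filter")
    return(empty_masks(dim(dna), min_area, exclude_border))
  }
  cell_bin <- cell01 > thr_cell | nuclei > 0
  cells <- EBImage::propagate(EBImage::Image(cell01), seeds = nuclei,
                              mask = cell_bin)
  nuclei_m <- as.integer(EBImage::imageData(nuclei))
  cells_m <- as.integer(EBImage::imageData(cells))
  dim(nuclei_m) <- dim(dna); dim(cells_m) <- dim(dna)
  # each nucleus lives in exactly one cell: clip nuclei to their own cell
  nuclei_m[nuclei_m != cells_m] <- 0L
  if (exclude_border) {
    border_labels <- unique(c(cells_m[1, ], cells_m[nrow(cells_m), ],
                              cells_m[, 1], cells_m[, ncol(cells_m)]))
    border_labels <- setdiff(border_labels, 0L)
    cells_m[cells_m %in% border_labels] <- 0L
    nuclei_m[nuclei_m %in% border_labels] <- 0L
  }
  keep <- intersect(unique(nuclei_m[nuclei_m > 0]), unique(cells_m[cells_m > 0]))
  cells_m[!cells_m %in% keep] <- 0L
  nuclei_m[!nuclei_m %in% keep] <- 0L
  structure(
    list(nuclei = nuclei_m, cells = cells_m,
         params = list(threshold_method = "otsu",
                       dna_threshold = as.numeric(thr_dna),
                       cell_threshold = as.numeric(thr_cell),
                       min_area = min_area, exclude_border = exclude_border)),
    class = "cell_masks"
  )
}

empty_masks <- function(dims, min_area, exclude_border) {
  structure(
    list(nuclei = matrix(0L, dims[1], dims[2]),
         cells = matrix(0L, dims[1], dims[2]),
         params = list(threshold_method = "otsu", dna_threshold = NA_real_,
                       cell_threshold = NA_real_, min_area = min_area,
                       exclude_border = exclude_border)),
    class = "cell_masks"
  )
}

#' Per-cell nuclear/cytoplasmic intensity ratio
#'
#' For each segmented cell, the mean target-channel intensity over the
#' nucleus mask and over the cytoplasm (cell minus nucleus), and their
#' ratio. Cells whose cytoplasm mask is empty are dropped with a warning.
#'
#' @param masks A [segment_cells()] result (or any list with integer label
#'   matrices `nuclei` and `cells` sharing label ids).
#' @param target Numeric intensity matrix, same dimensions as the masks.
#' @return Tibble with one row per cell: `cell_id`, `nuclear_mean`,
#'   `cytoplasmic_mean`, `ratio`, `nucleus_area`, `cytoplasm_area`.
#' @export
measure_nc_ratio <- function(masks, target) {
  stopifnot(is.list(masks), !is.null(masks$nuclei), !is.null(masks$cells))
  if (!all(dim(target) == dim(masks$nuclei))) {
    rlang::abort("target channel dimensions differ from masks")
  }
  labels <- sort(intersect(unique(masks$nuclei[masks$nuclei > 0]),
                           unique(masks$cells[masks$cells > 0])))
  rows <- purrr::map(labels, function(i) {
    nuc <- masks$nuclei == i
    cyto <- masks$cells == i & !nuc
    if (!any(cyto)) return(NULL)
    nm <- mean(target[nuc]); cm <- mean(target[cyto])
    tibble(cell_id = i, nuclear_mean = nm, cytoplasmic_mean = cm,
           ratio = nm / cm, nucleus_area = sum(nuc), cytoplasm_area = sum(cyto))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    rlang::warn(sprintf("%d cell(s) with empty cytoplasm dropped", dropped))
  }
  dplyr::bind_rows(rows)
}

#' Compare nuclear/cytoplasmic ratios between two groups
#'
#' Five-number box-and-whisker summaries per group (whiskers at 1.5 x IQR,
#' the conventional Tukey rule) and a two-sided two-sample Student's t-test
#' on the per-cell ratios (Welch's correction by flag).
#'
#' @param data Data frame with one row per cell.
#' @param value Name of the ratio column; default `"ratio"`.
#' @param group Name of the two-level grouping column; default `"group"`.
#' @param var_equal Classical Student's test with pooled variance (default
#'   TRUE); set FALSE for Welch.
#' @return An `nc_comparison`: list with `summary` (per-group tibble of n,
#'   median, quartiles and whisker ends), `test` (the `htest`), and
#'   `var_equal`. See [tidy.nc_comparison()] / [glance.nc_comparison()].
#' @export
compare_nc_groups <- function(data, value = "ratio", group = "group",
                              var_equal = TRUE) {
  data <- as_tibble(data)
  assert_columns(data, c(value, group), "`data`")
  groups <- unique(data[[group]])
  if (length(groups) != 2) rlang::abort("`group` must have exactly 2 levels")
  split_vals <- split(data[[value]], data[[group]])
  if (any(vapply(split_vals, length, integer(1)) < 2)) {
    rlang::abort("each group needs n >= 2")
  }
  summary <- purrr::imap_dfr(split_vals, function(v, g) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    tibble(
      group = g, n = length(v),
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
      whisker_high = max(v[v <= q[3] + 1.5 * iqr]),
      mean = mean(v), sd = sd(v)
    )
  })
  test <- t.test(split_vals[[1]], split_vals[[2]], var.equal = var_equal)
  structure(list(summary = summary, test = test, var_equal = var_equal,
                 value = value, group = group, data = data),
            class = "nc_comparison")
}

#' @export
print.nc_comparison <- function(x, ...) {
  cat(sprintf("<nc_comparison: %s t-test, t = %.3f, df = %.1f, p = %.3g>\n",
              if (x$var_equal) "Student's" else "Welch's",
              x$test$statistic, x$test$parameter, x$test$p.value))
  print(x$summary)
  invisible(x)
}

#' Tidy per-group summaries of an N/C ratio comparison
#'
#' @param x An [compare_nc_groups()] result.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @export
tidy.nc_comparison <- function(x, ...) {
  x$summary
}

#' One-row test summary of an N/C ratio comparison
#'
#' @param x An [compare_nc_groups()] result.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (group-mean difference),
#'   `statistic`, `df`, `p.value`, `method`.
#' @export
glance.nc_comparison <- function(x, ...) {
  tibble(
    estimate = unname(diff(rev(x$test$estimate))),
    statistic = unname(x$test$statistic),
    df = unname(x$test$parameter),
    p.value = x$test$p.value,
    method = x$test$method
  )
}

#' @describeIn compare_nc_groups Box-and-whisker plot of the two groups
#'   (whiskers at 1.5 x IQR).
#' @param object An `nc_comparison`.
#' @param ... Unused.
#' @export
autoplot.nc_comparison <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(.data[[object$group]],
                                   .data[[object$value]])) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "nuclear / cytoplasmic ratio",
                  subtitle = sprintf("%s, p = %.2g",
                                     object$test$method, object$test$p.value)) +
    ggplot2::theme_classic()
}
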