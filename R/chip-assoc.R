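# Peak-to-gene association: binary bin matrices over gene windows and the
# exponential distance-decay TSS score.

#' Binary factor-by-bin binding matrix over gene windows
#'
#' Tiles the region `[gene_start - window, gene_end + window)` of every gene
#' into `bin`-bp bins and marks, for each factor, the bins overlapped by at
#' least one retained peak interval (any overlap, not summit containment).
#' Overlapping gene windows contribute the union of their bins; identical
#' bins are collapsed.
#'
#' @param peak_sets Named list of peak tibbles (`chrom`, `start`, `end`),
#'   one per factor.
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param window Flank added on both sides of the gene body (bp); default 25000.
#' @param bin Bin width (bp); default 1000. Must not exceed `window`.
#' @return A `bin_matrix`: list with `matrix` (factors x bins, 0/1) and
#'   `bins` (tibble `chrom`, `start`, `end`, `column` mapping each column to
#'   its genomic bin).
#' @export
build_bin_matrix <- function(peak_sets, genes, window = 25000, bin = 1000) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  if (is.null(names(peak_sets)) || any(names(peak_sets) == "")) {
    rlang::abort("`peak_sets` must be a named list (one factor per element)")
  }
  if (!(window > 0 && bin > 0 && bin <= window)) {
    rlang::abort("need window > 0, bin > 0 and bin <= window")
  }
  genes <- as_tibble(genes)
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "`genes`")

  bins <- genes |>
    dplyr::mutate(win_start = .data$start - window,
                  win_end = .data$end + window) |>
    dplyr::reframe(
      start = seq(.data$win_start, .data$win_end - 1, by = bin),
      .by = c("gene_id", "chrom", "win_start", "win_end")
    ) |>
    dplyr::mutate(end = .data$start + bin) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(column = dplyr::row_number())

  mat <- matrix(0L, nrow = length(peak_sets), ncol = nrow(bins),
                dimnames = list(names(peak_sets), NULL))
  for (f in names(peak_sets)) {
    pk <- as_tibble(peak_sets[[f]])
    assert_columns(pk, c("chrom", "start", "end"), sprintf("peaks of %s", f))
    if (nrow(pk) == 0) next
    for (cm in unique(bins$chrom)) {
      b <- bins[bins$chrom == cm, ]
      p <- pk[pk$chrom == cm, ]
      if (nrow(p) == 0) next
      # half-open overlap: peak [s, e) overlaps bin [bs, be) iff s < be && e > bs
      hit <- vapply(seq_len(nrow(b)), function(i) {
        any(p$start < b$end[i] & p$end > b$start[i])
      }, logical(1))
      mat[f, b$column[hit]] <- 1L
    }
  }
  structure(list(matrix = mat, bins = bins, window = window, bin = bin),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix: %d factor(s) x %d genomic bin(s), window %d bp, bin %d bp>\n",
              nrow(x$matrix), ncol(x$matrix), x$window, x$bin))
  invisible(x)
}

#' Exponential distance-decay association of factors with genes
#'
#' Scores the association of each factor with each gene as
#' `sum_i exp(-d_i / decay)` over the factor's peaks `i`, where `d_i` is the
#' distance (bp) from the peak summit to the gene's TSS. By default only
#' peaks whose summit lies within `window` of the anchor are summed
#' (contributions from farther peaks are below `exp(-window/decay)` and
#' negligible); `global = TRUE` sums all same-chromosome peaks. With
#' `anchor = "gene"` a peak qualifies when its summit falls in the gene body
#' extended by `window` on both sides (distance is still summit-to-TSS).
#'
#' A gene is `bound` by a factor when at least one peak qualifies.
#'
#' @param peak_sets Named list of peak tibbles (`chrom`, `summit`), one per
#'   factor; typically [filter_peaks()] output.
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`, `strand`;
#'   a `tss` column is derived if absent (start for `+`, end - 1 for `-`).
#' @param window Qualification window (bp); default 25000.
#' @param decay Exponential decay length (bp); default 5000.
#' @param anchor Window anchoring: `"tss"` (default) or `"gene"` body.
#' @param global Sum over all same-chromosome peaks instead of the window.
#' @return Tibble with `factor`, `gene_id`, `n_peaks`, `score`, `bound`.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 50000,
#'                         end = 52000, strand = "+")
#' pks <- list(TF = tibble::tibble(chrom = "chr1", summit = c(50000, 55000)))
#' association_scores(pks, genes)$score # 1 + exp(-1)
#' @export
association_scores <- function(peak_sets, genes, window = 25000, decay = 5000,
                               anchor = c("tss", "gene"), global = FALSE) {
  anchor <- match.arg(anchor)
  if (!(window > 0 && decay > 0)) rlang::abort("need window > 0 and decay > 0")
  genes <- add_tss(as_tibble(genes))
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  purrr::imap_dfr(peak_sets, function(pk, f) {
    pk <- as_tibble(pk)
    assert_columns(pk, c("chrom", "summit"), sprintf("peaks of %s", f))
    purrr::pmap_dfr(
      list(genes$gene_id, genes$chrom, genes$start, genes$end, genes$tss),
      function(gid, cm, gs, ge, tss) {
        s <- pk$summit[pk$chrom == cm]
        keep <- if (global) {
          rep(TRUE, length(s))
        } else if (anchor == "tss") {
          abs(s - tss) <= window
        } else {
          s >= gs - window & s < ge + window
        }
        d <- abs(s[keep] - tss)
        tibble(factor = f, gene_id = gid, n_peaks = length(d),
               score = sum(exp(-d / decay)), bound = length(d) > 0)
      }
    )
  })
}

# TSS under BED half-open convention: start for +, end - 1 for -.
add_tss <- function(genes) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "`genes`")
  if ("tss" %in% names(genes)) return(genes)
  if (!"strand" %in% names(genes)) {
    rlang::abort("`genes` needs a `strand` column (or a precomputed `tss`)")
  }
  dplyr::mutate(genes,
                tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))
}

#' Per-factor bound-gene sets
#'
#' @param assoc Output of [association_scores()].
#' @return Named list of gene-id character vectors, one per factor.
#' @export
bound_genes <- function(assoc) {
  assoc <- as_tibble(assoc)
  assert_columns(assoc, c("factor", "gene_id", "bound"), "`assoc`")
  bound <- dplyr::filter(assoc, .data$bound)
  sets <- split(bound$gene_id, bound$factor)
  # factors with no bound gene still get an (empty) entry
  all_factors <- unique(assoc$factor)
  out <- setNames(vector("list", length(all_factors)), all_factors)
  for (f in all_factors) out[[f]] <- sets[[f]] %||% character()
  out
}

#' Pairwise overlap of bound-gene sets between factors
#'
#' The substrate of a Venn-style comparison of genes predicted bound by
#' different factors.
#'
#' @param assoc Output of [association_scores()].
#' @return Tibble with one row per unordered factor pair: `factor_a`,
#'   `factor_b`, `n_a`, `n_b`, `n_shared`.
#' @export
bound_gene_overlap <- function(assoc) {
  sets <- bound_genes(assoc)
  fs <- names(sets)
  if (length(fs) < 2) rlang::abort("need >= 2 factors to compute overlaps")
  pairs <- utils::combn(fs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(factor_a = a, factor_b = b,
           n_a = length(sets[[a]]), n_b = length(sets[[b]]),
           n_shared = length(intersect(sets[[a]], sets[[b]])))
  })
}

#' Enrichment of bound genes at the top of a ranked list
#'
#' Takes the first `floor(q * N)` genes of a ranked table (e.g. genes ranked
#' by up- or downregulation), computes the enrichment of a bound-gene set in
#' that slice over its genome-wide fraction, and a hypergeometric upper-tail
#' p-value (at least as many bound genes in the slice). A permutation mode
#' shuffles the ranking instead.
#'
#' @param ranked Tibble with a `gene_id` column, ordered from most to least
#'   extreme.
#' @param bound Character vector of bound gene ids; must be a subset of the
#'   ranked universe.
#' @param q Top quantile, in (0, 1); default 0.05 (the 2% slice is the other
#'   conventional choice).
#' @param method `"hypergeometric"` (default) or `"permutation"`.
#' @param n_perm Number of shuffles for the permutation mode.
#' @param seed Seed for the permutation mode.
#' @return One-row tibble: `q`, `n_genes`, `n_top`, `n_bound`,
#'   `n_bound_top`, `enrichment`, `p_value`.
#' @export
rank_enrichment <- function(ranked, bound, q = 0.05,
                            method = c("hypergeometric", "permutation"),
                            n_perm = 1e4, seed = NULL) {
  method <- match.arg(method)
  ranked <- as_tibble(ranked)
  assert_columns(ranked, "gene_id", "`ranked`")
  if (!(q > 0 && q < 1)) rlang::abort("`q` must be in (0, 1)")
  universe <- ranked$gene_id
  if (anyDuplicated(universe)) rlang::abort("ranked gene ids must be unique")
  stray <- setdiff(bound, universe)
  if (length(stray) > 0) {
    rlang::abort(sprintf("bound gene(s) not in ranked universe: %s",
                         paste(head(stray, 3), collapse = ", ")))
  }
  N <- length(universe)
  n_top <- floor(q * N)
  if (n_top < 1) rlang::abort("top slice is empty; increase q or the universe")
  K <- length(unique(bound))
  k <- sum(universe[seq_len(n_top)] %in% bound)
  enrichment <- (k / n_top) / (K / N)
  p <- if (method == "hypergeometric") {
    phyper(k - 1, K, N - K, n_top, lower.tail = FALSE)
  } else {
    with_seed(seed, {
      is_bound <- universe %in% bound
      perm <- vapply(seq_len(n_perm), function(i) {
        sum(sample(is_bound, n_top))
      }, numeric(1))
      mean(perm >= k)
    })
  }
  tibble(q = q, n_genes = N, n_top = n_top, n_bound = K,
         n_bound_top = k, enrichment = enrichment, p_value = p)
}
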