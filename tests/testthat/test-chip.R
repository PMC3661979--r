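test_that("deduplication keeps one read per (chrom, start, strand) and is idempotent", {
  r <- make_reads("chr1", c(100, 100, 100), c("+", "+", "-"))
  expect_equal(nrow(dedup_reads(r)), 2L)

  uniq <- make_reads("chr1", 1:10)
  expect_equal(dedup_reads(uniq), uniq)

  set.seed(21)
  for (i in 1:5) {
    rr <- random_reads(200, max_pos = 50) # heavy collisions
    once <- dedup_reads(rr)
    expect_equal(dedup_reads(once), once)
    expect_equal(nrow(once), nrow(dplyr::distinct(rr, chrom, start, strand)))
  }
})

test_that("equal-depth subsampling honours the min-size, subset and seed contracts", {
  set.seed(31)
  sets <- list(a = random_reads(120), b = random_reads(80), c = random_reads(100))
  out <- subsample_equal(sets, seed = 5)
  expect_equal(unname(vapply(out, nrow, integer(1))), c(80L, 80L, 80L))
  for (nm in names(sets)) {
    expect_true(all(do.call(paste, out[[nm]]) %in% do.call(paste, sets[[nm]])))
  }
  # equal sizes: output is the input up to order
  eq <- list(x = random_reads(50), y = random_reads(50))
  out_eq <- subsample_equal(eq, seed = 1)
  expect_equal(dplyr::arrange(out_eq$x, chrom, start, strand),
               dplyr::arrange(eq$x, chrom, start, strand))
  # seed contract
  expect_identical(subsample_equal(sets, seed = 5), out)
  expect_false(identical(subsample_equal(sets, seed = 6), out))
  expect_error(subsample_equal(list(a = random_reads(0))), "empty")
})

test_that("fold-enrichment filtering is inclusive at the boundary", {
  pk <- make_peaks("chr1", c(0, 100, 200), c(50, 150, 250),
                   fold = c(99.9, 100, 250))
  expect_equal(nrow(filter_peaks(pk)), 2L)
  expect_equal(filter_peaks(pk, min_fold = 0), pk)
  expect_error(filter_peaks(dplyr::select(pk, -fold_enrichment)),
               "fold_enrichment")

  set.seed(41)
  folds <- runif(50, 0, 300)
  pk2 <- make_peaks("chr1", seq(0, by = 100, length.out = 50),
                    seq(50, by = 100, length.out = 50), fold = folds)
  expect_equal(filter_peaks(pk2, 120)$name, pk2$name[folds >= 120])
})

test_that("peak statistics report count and mean width", {
  expect_equal(peak_stats(make_peaks("chr1", 100, 700))$mean_width, 600)
  pk <- make_peaks("chr1", c(0, 1000), c(500, 1700))
  expect_equal(peak_stats(pk)$mean_width, 600)
  set.seed(51)
  s <- sample.int(1e4, 20); w <- sample.int(900, 20)
  expect_equal(peak_stats(make_peaks("chr1", s, s + w))$mean_width, mean(w))
})

test_that("read density counts starts in the half-open peak and scales per kb", {
  pk <- make_peaks("chr1", 1000, 2000)
  rd <- make_reads("chr1", seq(1000, 1999, length.out = 50))
  expect_equal(read_density(pk, rd)$density, 50)
  pk2 <- make_peaks("chr1", 1000, 3000)
  expect_equal(read_density(pk2, rd)$density, 25)

  set.seed(61)
  for (i in 1:5) {
    peaks <- make_peaks(sample(c("chr1", "chr2"), 10, replace = TRUE),
                        s <- sample.int(900, 10), s + sample.int(300, 10))
    reads <- random_reads(500)
    got <- read_density(peaks, reads)
    expect_equal(got$n_reads, as.integer(naive_peak_counts(peaks, reads)))
    expect_equal(got$density,
                 naive_peak_counts(peaks, reads) / ((peaks$end - peaks$start) / 1000))
  }
})

test_that("bin matrix tiles gene windows and matches a brute-force overlap scan", {
  genes <- make_genes("chr1", 100000, 102000)
  bm <- build_bin_matrix(list(TF = make_peaks("chr1", 100500, 101100)), genes)
  expect_equal(ncol(bm$matrix), 52L) # (2000 + 50000) / 1000
  expect_equal(bm$bins$start[1], 75000)
  expect_true(all(bm$matrix %in% c(0L, 1L)))

  # no peaks -> all-zero matrix
  bm0 <- build_bin_matrix(
    list(TF = make_peaks("chr1", integer(), integer())), genes)
  expect_true(all(bm0$matrix == 0))

  # a peak spanning a bin boundary marks both bins
  pk <- make_peaks("chr1", 99950, 100050)
  bm2 <- build_bin_matrix(list(TF = pk), genes)
  marked <- bm$bins[which(bm2$matrix[1, ] == 1L), ]
  expect_equal(marked$start, c(99000, 100000))

  # brute-force oracle on a random small genome (<= 1e5 bp)
  set.seed(71)
  genes_r <- make_genes("chr1", c(30000, 60000), c(32000, 61000),
                        strand = c("+", "-"))
  for (i in 1:3) {
    s <- sample.int(9e4, 30)
    peaks_r <- list(A = make_peaks("chr1", s, s + sample.int(2000, 30)),
                    B = make_peaks("chr1", rev(s) + 500, rev(s) + 1500))
    bmr <- build_bin_matrix(peaks_r, genes_r, window = 5000, bin = 500)
    for (f in names(peaks_r)) {
      expect_equal(unname(bmr$matrix[f, ]), naive_bin_row(peaks_r[[f]], bmr$bins))
    }
  }
})

test_that("association score follows the exponential distance decay exactly", {
  genes <- make_genes("chr1", 50000, 52000) # TSS at 50000
  score_for <- function(summits) {
    association_scores(
      list(TF = make_peaks("chr1", summits - 300, summits + 300, summit = summits)),
      genes
    )$score
  }
  expect_equal(score_for(50000), 1, tolerance = 1e-7)
  expect_equal(score_for(55000), exp(-1), tolerance = 1e-7)
  expect_equal(score_for(c(50000, 55000, 75000)), 1 + exp(-1) + exp(-5),
               tolerance = 1e-7)

  # additive over peaks and invariant to peak order
  expect_equal(score_for(c(55000, 50000, 75000)),
               score_for(50000) + score_for(55000) + score_for(75000))
  # bounded above by the number of peaks
  set.seed(81)
  summits <- 50000 + sample(-20000:20000, 10)
  expect_lte(score_for(summits), 10)
  # strictly decreasing in distance
  expect_gt(score_for(51000), score_for(52000))
})

test_that("window anchoring and the global switch behave as documented", {
  # gene body [50000, 60000), TSS 50000; summit at 59000 + 20000 = 79000 is
  # outside the TSS window (d = 29000) but inside gene_end + 25000
  genes <- make_genes("chr1", 50000, 60000)
  pk <- list(TF = make_peaks("chr1", 78700, 79300, summit = 79000))
  tss_scores <- association_scores(pk, genes, anchor = "tss")
  gene_scores <- association_scores(pk, genes, anchor = "gene")
  expect_false(tss_scores$bound)
  expect_true(gene_scores$bound)
  expect_equal(gene_scores$score, exp(-29000 / 5000))
  glob <- association_scores(pk, genes, global = TRUE)
  expect_equal(glob$score, exp(-29000 / 5000))
})

test_that("bound-gene sets come from peak presence within the window", {
  set.seed(91)
  genes <- make_genes("chr1", seq(50000, 450000, by = 100000),
                      seq(52000, 452000, by = 100000))
  summits <- sample.int(5e5, 40)
  pk <- list(A = make_peaks("chr1", summits - 100, summits + 100, summit = summits))
  assoc <- association_scores(pk, genes)
  sets <- bound_genes(assoc)
  manual <- genes$gene_id[vapply(genes$tss, function(t) {
    any(abs(summits - t) <= 25000)
  }, logical(1))]
  expect_setequal(sets$A, manual)
  # bound implies positive score
  expect_true(all(assoc$score[assoc$bound] > 0))
  expect_true(all(assoc$score[!assoc$bound] == 0))
})

test_that("bound-gene overlap counts shared genes per factor pair", {
  assoc <- tibble::tibble(
    factor = rep(c("A", "B"), each = 4),
    gene_id = c("g1", "g2", "g3", "g4", "g2", "g3", "g4", "g5"),
    bound = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  ov <- bound_gene_overlap(assoc)
  expect_equal(ov$n_a, 3); expect_equal(ov$n_b, 3)
  expect_equal(ov$n_shared, 2) # g2, g3
})

test_that("nearest-factor distances match the all-pairs oracle", {
  q <- make_peaks("chr1", 9700, 10300, summit = 10000)
  o <- make_peaks("chr1", c(7700, 29700), c(8300, 30300),
                  summit = c(8000, 30000))
  expect_equal(nearest_factor_distance(q, o)$nearest_distance, 2000)
  expect_equal(nearest_factor_distance(q, q)$nearest_distance, 0)

  set.seed(101)
  for (i in 1:5) {
    qs <- sample.int(1e5, 20); os <- sample.int(1e5, 30)
    qq <- make_peaks(sample(c("chr1", "chr2"), 20, replace = TRUE),
                     qs, qs + 100, summit = qs + 50)
    oo <- make_peaks(sample(c("chr1", "chr3"), 30, replace = TRUE),
                     os, os + 100, summit = os + 50)
    expect_equal(nearest_factor_distance(qq, oo)$nearest_distance,
                 naive_nearest(qq, oo))
  }
})

test_that("rank enrichment reproduces the exact hypergeometric tail", {
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:20))
  bound <- sprintf("g%02d", c(1, 2, 3, 10, 15)) # 3 of 5 in the top 4
  out <- rank_enrichment(ranked, bound, q = 0.2)
  expect_equal(out$n_top, 4)
  expect_equal(out$n_bound_top, 3)
  expect_equal(out$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(out$enrichment, (3 / 4) / (5 / 20))

  # equal representation (1 of 4 in the slice, 5 of 20 overall) -> enrichment 1
  ranked2 <- tibble::tibble(gene_id = sprintf("g%02d", 1:20))
  out2 <- rank_enrichment(ranked2, sprintf("g%02d", c(1, 5, 10, 15, 20)), q = 0.2)
  expect_equal(out2$enrichment, 1)

  expect_error(rank_enrichment(ranked, bound, q = 0.01), "empty")
  expect_error(rank_enrichment(ranked, "nope", q = 0.2), "universe")
})

test_that("permutation and hypergeometric enrichment p-values agree", {
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:20))
  bound <- sprintf("g%02d", c(1, 2, 3, 10, 15))
  p_hyper <- rank_enrichment(ranked, bound, q = 0.2)$p_value
  p_perm <- rank_enrichment(ranked, bound, q = 0.2, method = "permutation",
                            n_perm = 2e4, seed = 9)$p_value
  expect_lt(abs(p_perm - p_hyper), 4 * sqrt(p_hyper * (1 - p_hyper) / 2e4))
})

test_that("profile clustering uses 1 - Pearson r and merges planted blocks first", {
  m <- rbind(a = c(1, 0, 1, 0, 1, 1), b = c(1, 0, 1, 0, 1, 1),
             c = c(0, 1, 0, 1, 0, 0))
  cl <- cluster_profiles(m)
  expect_equal(cl$cor["a", "b"], 1)
  expect_equal(min(cl$hclust$height), 0) # identical rows merge at distance 0
  expect_equal(cl$cor["a", "c"], -1)     # anti-correlated -> distance 2
  expect_equal(max(1 - cl$cor), 2)

  # planted block structure: the two within-block pairs merge before any
  # cross-block join
  set.seed(111)
  base1 <- rbinom(200, 1, 0.3); base2 <- rbinom(200, 1, 0.3)
  flip <- function(x, k) { i <- sample.int(200, k); x[i] <- 1 - x[i]; x }
  m4 <- rbind(A1 = base1, A2 = flip(base1, 8),
              B1 = base2, B2 = flip(base2, 8))
  cl4 <- cluster_profiles(m4)
  first_two <- cl4$hclust$merge[1:2, ]
  expect_true(all(first_two < 0)) # both first merges join single factors
  merged_pairs <- lapply(1:2, function(i) sort(rownames(m4)[-first_two[i, ]]))
  expect_setequal(merged_pairs, list(c("A1", "A2"), c("B1", "B2")))

  # zero-variance rows are dropped with a warning
  expect_warning(cluster_profiles(rbind(m, d = c(1, 1, 1, 1, 1, 1))),
                 "zero-variance")
  expect_error(suppressWarnings(
    cluster_profiles(rbind(a = c(1, 1), b = c(2, 2)))
  ), ">= 2")
})
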