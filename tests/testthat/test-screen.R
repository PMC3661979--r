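test_that("plate normalization divides by the on-plate control mean", {
  tbl <- tibble::tibble(
    plate = 1L, well = c("A01", "A02", "A03"), replicate = 1L,
    sirna_id = c("CONTROL", "CONTROL", "si_x"),
    gene_id = c(NA, NA, "x"), raw = c(90, 110, 80)
  )
  out <- normalize_plate(tbl)
  expect_equal(out$normalized[out$sirna_id == "si_x"], 0.8)
  # controls normalize to mean 1
  expect_equal(mean(out$normalized[out$sirna_id == "CONTROL"]), 1)

  # all wells equal -> everything normalizes to 1
  flat <- dplyr::mutate(tbl, raw = 250)
  expect_true(all(normalize_plate(flat)$normalized == 1))
})

test_that("normalization errors name the offending plate", {
  tbl <- tibble::tibble(
    plate = c(1L, 2L), well = "A01", replicate = 1L,
    sirna_id = c("CONTROL", "si_x"), gene_id = c(NA, "x"), raw = c(100, 50)
  )
  expect_error(normalize_plate(tbl), "plate 2")
  zero <- tibble::tibble(plate = 3L, well = "A01", replicate = 1L,
                         sirna_id = "CONTROL", gene_id = NA, raw = 0)
  expect_error(normalize_plate(zero), "plate 3")
  expect_error(normalize_plate(dplyr::mutate(zero, raw = -1)), ">= 0")
})

test_that("z-scores standardize gene values within each run (sample sd)", {
  tbl <- tibble::tibble(
    plate = 1L, well = sprintf("A%02d", 1:3), replicate = 1L,
    sirna_id = sprintf("si%d", 1:3), gene_id = sprintf("g%d", 1:3),
    normalized = c(1, 2, 3)
  )
  z <- screen_zscores(tbl)
  expect_equal(z$z[order(z$gene_id)], c(-1, 0, 1))

  # location invariance: adding a constant leaves z unchanged
  shifted <- dplyr::mutate(tbl, normalized = normalized + 7)
  expect_equal(screen_zscores(shifted)$z, z$z)

  # degenerate run: zero dispersion
  flat <- dplyr::mutate(tbl, normalized = 1)
  expect_error(screen_zscores(flat), "degenerate")
})

test_that("z-scores are invariant to rescaling any single plate", {
  plates <- simulate_screen(screen_sim_config(n_genes = 170, seed = 5))
  z_ref <- screen_zscores(normalize_plate(plates))
  scaled <- dplyr::mutate(plates,
                          raw = raw * ifelse(plate == 2 & replicate == 1, 7, 1))
  z_scaled <- screen_zscores(normalize_plate(scaled))
  expect_equal(z_scaled$z, z_ref$z, tolerance = 1e-12)
})

test_that("dual-threshold hit calling is order-agnostic and matches a grid oracle", {
  z_pair <- function(z1, z2) {
    tibble::tibble(gene_id = "g", sirna_id = "s", replicate = c(1L, 2L),
                   z = c(z1, z2))
  }
  expect_true(call_hits(z_pair(3.2, 2.6))$screen_positive)
  expect_true(call_hits(z_pair(2.6, 3.2))$screen_positive)
  expect_false(call_hits(z_pair(3.2, 2.4))$screen_positive)
  # the ordered variant is stricter
  expect_false(call_hits(z_pair(2.6, 3.2), order_agnostic = FALSE)$screen_positive)
  expect_true(call_hits(z_pair(3.2, 2.6), order_agnostic = FALSE)$screen_positive)

  # exhaustive grid against a direct evaluation of the rule
  grid <- expand.grid(z1 = seq(-1, 4, by = 0.25), z2 = seq(-1, 4, by = 0.25))
  ids <- sprintf("g%04d", seq_len(nrow(grid)))
  z_tbl <- tibble::tibble(
    gene_id = rep(ids, each = 2),
    replicate = rep(c(1L, 2L), nrow(grid)),
    z = as.vector(rbind(grid$z1, grid$z2))
  )
  called <- call_hits(z_tbl)
  oracle <- pmax(grid$z1, grid$z2) > 3 & pmin(grid$z1, grid$z2) > 2.5
  expect_equal(called$screen_positive[match(ids, called$gene_id)], oracle)
})

test_that("genes without two replicates are unscorable, with a warning", {
  z_tbl <- tibble::tibble(gene_id = c("a", "a", "b"),
                          replicate = c(1L, 2L, 1L), z = c(4, 4, 4))
  expect_warning(out <- call_hits(z_tbl), "unscorable")
  expect_equal(out$gene_id, "a")
})

test_that("gene-level collapse over duplicated library entries keeps the best entry", {
  z_tbl <- tibble::tibble(
    gene_id = "g", sirna_id = c("s1", "s1", "s2", "s2"),
    replicate = c(1L, 2L, 1L, 2L), z = c(3.5, 1.0, 3.6, 2.8)
  )
  out <- call_hits(z_tbl)
  expect_equal(nrow(out), 1L)
  expect_true(out$screen_positive) # entry s2 passes, s1 does not
})

test_that("null false-positive probability matches its closed form and Monte Carlo", {
  # frozen closed form: 2*Q(3)*Q(2.5) - Q(3)^2
  expect_equal(false_positive_probability(), 1.4942605305e-05, tolerance = 1e-9)
  expect_equal(false_positive_probability(0, 0), 0.25)
  expect_lt(false_positive_probability(), 0.01)
  # ordered rule: Q(3) * Q(2.5)
  expect_equal(false_positive_probability(order_agnostic = FALSE),
               pnorm(3, lower.tail = FALSE) * pnorm(2.5, lower.tail = FALSE))
  # Monte-Carlo cross-check at loose thresholds (ample counts)
  p_cf <- false_positive_probability(1.5, 1)
  p_mc <- false_positive_probability(1.5, 1, method = "monte_carlo",
                                     n_draws = 2e5, seed = 4)
  expect_lt(abs(p_mc - p_cf), 4 * sqrt(p_cf * (1 - p_cf) / 2e5))
  # correlated nulls are more likely to pass jointly
  expect_gt(false_positive_probability(correlation = 0.695),
            false_positive_probability())
  p_mc_corr <- false_positive_probability(1.5, 1, correlation = 0.5,
                                          method = "monte_carlo",
                                          n_draws = 2e5, seed = 8)
  p_cf_corr <- false_positive_probability(1.5, 1, correlation = 0.5)
  expect_lt(abs(p_mc_corr - p_cf_corr), 4 * sqrt(p_cf_corr / 2e5))
})

test_that("ledger arithmetic: primary hits = positives minus disjoint exclusions", {
  hits <- tibble::tibble(gene_id = sprintf("g%02d", 1:90),
                         screen_positive = c(rep(TRUE, 80), rep(FALSE, 10)))
  not_expressed <- sprintf("g%02d", 1:12)
  manual <- sprintf("g%02d", 13:17)
  ledger <- apply_ledger(hits,
                         expressed = setdiff(hits$gene_id, not_expressed),
                         manual_excluded = manual)
  prov <- glance(ledger)
  expect_equal(prov$n_screen_positive, 80)
  expect_equal(prov$n_expression_excluded, 12)
  expect_equal(prov$n_manual_excluded, 5)
  expect_equal(prov$n_primary_hits, 80 - 12 - 5)
  # conservation when exclusion sets are disjoint subsets of positives
  expect_equal(prov$n_screen_positive,
               prov$n_primary_hits + prov$n_expression_excluded +
                 prov$n_manual_excluded)
  # invariant: primary_hit implies screen_positive, expressed, not excluded
  expect_true(all(!ledger$primary_hit |
                    (ledger$screen_positive & ledger$expressed &
                       !ledger$manual_excluded)))

  # empty exclusions: primary = positives
  ledger0 <- apply_ledger(hits)
  expect_equal(glance(ledger0)$n_primary_hits, 80)
  # exclusion of a never-scored gene warns and is ignored
  expect_warning(apply_ledger(hits, manual_excluded = "nope"), "never scored")
})

test_that("validation requires at least two siRNAs above the fold threshold", {
  folds <- tibble::tibble(
    gene_id = rep(c("a", "b", "c"), c(4, 4, 1)),
    sirna_id = sprintf("s%d", c(1:4, 1:4, 1)),
    fold_change = c(2.5, 2.1, 1.5, 0.8, 1.9, 1.9, 1.9, 1.9, 2.1)
  )
  out <- call_validation(folds)
  expect_equal(out$validated[out$gene_id == "a"], TRUE)   # two above 2
  expect_equal(out$validated[out$gene_id == "b"], FALSE)  # none above 2
  expect_equal(out$validated[out$gene_id == "c"], FALSE)  # only one siRNA
})
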