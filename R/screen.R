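#' Percent-of-control plate normalization
#'
#' Divides every raw viability value by the mean raw value of the no-siRNA
#' control wells on the same plate and replicate, so controls normalize to
#' mean 1 per plate. This is the standard on-plate percent-of-control
#' normalization; it preserves positivity and is invariant to rescaling any
#' single plate.
#'
#' @param screen_tbl Screen table with columns `plate`, `replicate`,
#'   `sirna_id`, `raw`; control wells carry `sirna_id == "CONTROL"`.
#' @return The input tibble with a `normalized` column added.
#' @examples
#' plates <- simulate_screen(screen_sim_config(n_genes = 85, seed = 1))
#' normalize_plate(plates)
#' @export
normalize_plate <- function(screen_tbl) {
  screen_tbl <- as_tibble(screen_tbl)
  assert_columns(screen_tbl, c("plate", "replicate", "sirna_id", "raw"), "`screen_tbl`")
  if (any(screen_tbl$raw < 0, na.rm = TRUE)) {
    rlang::abort("raw viability must be >= 0")
  }
  ctrl <- screen_tbl |>
    dplyr::filter(.data$sirna_id == "CONTROL") |>
    dplyr::summarise(control_mean = mean(.data$raw),
                     .by = c("plate", "replicate"))
  missing <- screen_tbl |>
    dplyr::distinct(.data$plate, .data$replicate) |>
    dplyr::anti_join(ctrl, by = c("plate", "replicate"))
  if (nrow(missing) > 0) {
    rlang::abort(sprintf(
      "no CONTROL wells on plate(s): %s",
      paste(sprintf("plate %s replicate %s", missing$plate, missing$replicate),
            collapse = "; ")
    ))
  }
  bad <- ctrl$control_mean <= 0
  if (any(bad)) {
    rlang::abort(sprintf(
      "control mean <= 0, plate invalid: %s",
      paste(sprintf("plate %s replicate %s", ctrl$plate[bad], ctrl$replicate[bad]),
            collapse = "; ")
    ))
  }
  screen_tbl |>
    dplyr::left_join(ctrl, by = c("plate", "replicate")) |>
    dplyr::mutate(normalized = .data$raw / .data$control_mean) |>
    dplyr::select(-"control_mean")
}

#' Per-replicate Z-scores of normalized gene viability
#'
#' Standardizes gene-level normalized viability within each replicate run:
#' `z = (x - mean(x)) / sd(x)` over genes, with the sample (n-1) standard
#' deviation and control wells excluded. Library entries (siRNA pools) are
#' scored individually; gene-level collapse across duplicated entries takes
#' the maximum-z entry (see [call_hits()]).
#'
#' @param normalized_tbl Output of [normalize_plate()] (or any table with
#'   `replicate`, `sirna_id`, `gene_id` and a value column).
#' @param value Column to standardize; default `normalized`, set to `raw` to
#'   score unnormalized readouts.
#' @param transform `"identity"` (default) standardizes the values as they
#'   are; `"log"` standardizes their natural log. Viability readouts are
#'   positive and right-skewed (approximately log-normal), so raw-scale
#'   Z-scores have a heavier-than-normal upper tail and the normal-theory
#'   false-positive bound of [false_positive_probability()] understates the
#'   null hit rate; log-scale Z-scores restore normal calibration for
#'   log-normal noise.
#' @return Tibble with one row per (library entry, replicate):
#'   `sirna_id`, `gene_id`, `replicate`, `value`, `z`.
#' @export
screen_zscores <- function(normalized_tbl, value = "normalized",
                           transform = c("identity", "log")) {
  transform <- match.arg(transform)
  normalized_tbl <- as_tibble(normalized_tbl)
  assert_columns(normalized_tbl, c("replicate", "sirna_id", "gene_id", value),
                 "`normalized_tbl`")
  entries <- normalized_tbl |>
    dplyr::filter(.data$sirna_id != "CONTROL", !is.na(.data$gene_id)) |>
    dplyr::summarise(value = mean(.data[[value]]),
                     .by = c("sirna_id", "gene_id", "replicate"))
  if (transform == "log") {
    if (any(entries$value <= 0)) {
      rlang::abort("log transform requires strictly positive values")
    }
    entries$value <- log(entries$value)
  }
  counts <- dplyr::count(entries, .data$replicate)
  if (any(counts$n < 3)) {
    rlang::abort("need >= 3 scored genes per replicate to standardize")
  }
  out <- entries |>
    dplyr::mutate(
      z = {
        s <- sd(.data$value)
        if (!is.finite(s) || s == 0) {
          rlang::abort(sprintf("degenerate run: zero dispersion in replicate %s",
                               .data$replicate[1]))
        }
        (.data$value - mean(.data$value)) / s
      },
      .by = "replicate"
    )
  dplyr::arrange(out, .data$gene_id, .data$replicate)
}

#' Dual-replicate hit calling
#'
#' A gene is screen-positive when its two replicate Z-scores clear the dual
#' thresholds: by default order-agnostically, `max(z1, z2) > z_hi` and
#' `min(z1, z2) > z_lo` (the permissive reading of "Z > 3 and Z > 2.5 in the
#' two trials"); with `order_agnostic = FALSE` replicate 1 must exceed `z_hi`
#' and replicate 2 `z_lo`. Entries are first collapsed to genes by taking the
#' entry whose smaller replicate z is largest (max-entry collapse for
#' duplicated library entries).
#'
#' @param z_tbl Output of [screen_zscores()]; genes must have exactly 2
#'   replicates (others are flagged unscorable and dropped with a warning).
#' @param z_hi,z_lo Upper and lower thresholds (defaults 3 and 2.5);
#'   `z_hi >= z_lo > 0`.
#' @param order_agnostic Apply thresholds to the ordered pair
#'   (max, min) rather than to (replicate 1, replicate 2).
#' @return Tibble with `gene_id`, `z1`, `z2`, `screen_positive`.
#' @export
call_hits <- function(z_tbl, z_hi = 3, z_lo = 2.5, order_agnostic = TRUE) {
  if (!(z_hi >= z_lo && z_lo > 0)) rlang::abort("need z_hi >= z_lo > 0")
  z_tbl <- as_tibble(z_tbl)
  assert_columns(z_tbl, c("gene_id", "replicate", "z"), "`z_tbl`")
  n_rep <- z_tbl |>
    dplyr::distinct(.data$gene_id, .data$replicate) |>
    dplyr::count(.data$gene_id)
  unscorable <- n_rep$gene_id[n_rep$n != 2]
  if (length(unscorable) > 0) {
    rlang::warn(sprintf(
      "%d gene(s) without exactly 2 replicate z-scores are unscorable and excluded (e.g. %s)",
      length(unscorable), paste(head(unscorable, 3), collapse = ", ")
    ))
    z_tbl <- dplyr::filter(z_tbl, !.data$gene_id %in% unscorable)
  }
  wide <- z_tbl |>
    dplyr::mutate(.rep = match(.data$replicate, sort(unique(.data$replicate)))) |>
    tidyr::pivot_wider(id_cols = c("gene_id", dplyr::any_of("sirna_id")),
                       names_from = ".rep", values_from = "z",
                       names_prefix = "z")
  # gene-level collapse over duplicated library entries: keep the entry with
  # the largest min(z1, z2) (the one closest to passing the dual threshold)
  wide <- wide |>
    dplyr::slice_max(pmin(.data$z1, .data$z2), n = 1, with_ties = FALSE,
                     by = "gene_id")
  wide |>
    dplyr::mutate(
      screen_positive = if (order_agnostic) {
        pmax(.data$z1, .data$z2) > z_hi & pmin(.data$z1, .data$z2) > z_lo
      } else {
        .data$z1 > z_hi & .data$z2 > z_lo
      }
    ) |>
    dplyr::select("gene_id", "z1", "z2", "screen_positive") |>
    dplyr::arrange(.data$gene_id)
}

#' Null probability of passing the dual Z threshold
#'
#' Probability that a null gene is called screen-positive when its two
#' replicate Z-scores are standard normal. In closed form for independent
#' replicates the order-agnostic rule gives
#' `2 * Q(z_hi) * Q(z_lo) - Q(z_hi)^2` with `Q` the upper normal tail; with
#' `correlation > 0` the bivariate-normal orthant probabilities are computed
#' by one-dimensional quadrature. A Monte-Carlo mode cross-checks either.
#'
#' @param z_hi,z_lo Thresholds as in [call_hits()].
#' @param order_agnostic As in [call_hits()].
#' @param correlation Correlation of the two null Z-scores (default 0,
#'   independence).
#' @param method `"closed_form"` (default) or `"monte_carlo"`.
#' @param n_draws Number of Monte-Carlo gene draws.
#' @param seed Seed for the Monte-Carlo mode.
#' @return A single probability.
#' @examples
#' false_positive_probability()            # approx. 1.494e-5, well below 1%
#' false_positive_probability(0, 0)        # 0.25: both z > 0, independent
#' @export
false_positive_probability <- function(z_hi = 3, z_lo = 2.5,
                                       order_agnostic = TRUE,
                                       correlation = 0,
                                       method = c("closed_form", "monte_carlo"),
                                       n_draws = 1e7, seed = NULL) {
  method <- match.arg(method)
  if (z_hi < z_lo) rlang::abort("need z_hi >= z_lo")
  if (abs(correlation) >= 1) rlang::abort("`correlation` must be in (-1, 1)")
  if (method == "monte_carlo") {
    return(with_seed(seed, {
      z1 <- rnorm(n_draws)
      z2 <- correlation * z1 + sqrt(1 - correlation^2) * rnorm(n_draws)
      hit <- if (order_agnostic) {
        pmax(z1, z2) > z_hi & pmin(z1, z2) > z_lo
      } else {
        z1 > z_hi & z2 > z_lo
      }
      mean(hit)
    }))
  }
  tail2 <- function(a, b) bvn_upper_tail(a, b, correlation)
  if (order_agnostic) {
    tail2(z_hi, z_lo) + tail2(z_lo, z_hi) - tail2(z_hi, z_hi)
  } else {
    tail2(z_hi, z_lo)
  }
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation r,
# by integrating the conditional tail over the Z1 density.
bvn_upper_tail <- function(a, b, r) {
  if (r == 0) return(pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE))
  f <- function(z) {
    pnorm((b - r * z) / sqrt(1 - r^2), lower.tail = FALSE) * dnorm(z)
  }
  integrate(f, lower = a, upper = Inf, rel.tol = 1e-12)$value
}

#' Apply the expression and manual-exclusion ledger
#'
#' Intersects screen positives with the expressed-gene set and removes
#' manual exclusions: `primary_hit = screen_positive & expressed &
#' !manual_excluded`. Counts at every filter step are recorded as a
#' provenance attribute (retrievable with [glance()]).
#'
#' @param hits Output of [call_hits()] (needs `gene_id`, `screen_positive`).
#' @param expressed Character vector of expressed gene ids. `NULL` means no
#'   expression filter (all scored genes treated as expressed).
#' @param manual_excluded Character vector of manually eliminated gene ids.
#' @return A `hit_ledger` tibble: the input plus `expressed`,
#'   `manual_excluded`, `primary_hit` columns and a `provenance` attribute
#'   with counts (`n_screen_positive`, `n_expression_excluded`,
#'   `n_manual_excluded`, `n_primary_hits`).
#' @examples
#' hits <- tibble::tibble(gene_id = c("a", "b", "c"), z1 = c(4, 4, 1),
#'                        z2 = c(3, 3, 0), screen_positive = c(TRUE, TRUE, FALSE))
#' ledger <- apply_ledger(hits, expressed = c("a", "c"))
#' glance(ledger)
#' @export
apply_ledger <- function(hits, expressed = NULL, manual_excluded = character()) {
  hits <- as_tibble(hits)
  assert_columns(hits, c("gene_id", "screen_positive"), "`hits`")
  scored <- hits$gene_id
  for (set_name in c("expressed", "manual_excluded")) {
    set <- switch(set_name, expressed = expressed, manual_excluded = manual_excluded)
    unknown <- setdiff(set, scored)
    if (length(unknown) > 0) {
      rlang::warn(sprintf(
        "%d gene(s) in `%s` were never scored and are ignored (e.g. %s)",
        length(unknown), set_name, paste(head(unknown, 3), collapse = ", ")
      ))
    }
  }
  out <- hits |>
    dplyr::mutate(
      expressed = if (is.null(expressed)) TRUE else .data$gene_id %in% expressed,
      manual_excluded = .data$gene_id %in% manual_excluded,
      primary_hit = .data$screen_positive & .data$expressed & !.data$manual_excluded
    )
  prov <- list(
    n_scored = nrow(out),
    n_screen_positive = sum(out$screen_positive),
    n_expression_excluded = sum(out$screen_positive & !out$expressed),
    n_manual_excluded = sum(out$screen_positive & out$expressed & out$manual_excluded),
    n_primary_hits = sum(out$primary_hit)
  )
  attr(out, "provenance") <- prov
  class(out) <- c("hit_ledger", class(out))
  out
}

#' @export
glance.hit_ledger <- function(x, ...) {
  as_tibble(attr(x, "provenance"))
}

#' Multi-siRNA validation call
#'
#' A gene validates when at least `min_sirnas` of its individually retested
#' siRNAs increase viability more than `fold`-fold over the no-siRNA control
#' (an increase greater than 2-fold is considered significant by default).
#'
#' @param fold_tbl Tibble with columns `gene_id`, `sirna_id`, `fold_change`
#'   (viability fold over no-siRNA control).
#' @param fold Fold-change threshold, strict (> `fold`); default 2.
#' @param min_sirnas Minimum number of siRNAs that must pass; default 2.
#' @return Tibble with `gene_id`, `n_sirnas`, `n_validating`, `validated`.
#' @export
call_validation <- function(fold_tbl, fold = 2, min_sirnas = 2) {
  if (!(fold > 1)) rlang::abort("`fold` must be > 1")
  fold_tbl <- as_tibble(fold_tbl)
  assert_columns(fold_tbl, c("gene_id", "fold_change"), "`fold_tbl`")
  fold_tbl |>
    dplyr::summarise(
      n_sirnas = dplyr::n(),
      n_validating = sum(.data$fold_change > fold),
      .by = "gene_id"
    ) |>
    dplyr::mutate(validated = .data$n_validating >= min_sirnas) |>
    dplyr::arrange(.data$gene_id)
}
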