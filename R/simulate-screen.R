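#' Configuration for the synthetic arrayed RNAi screen
#'
#' Describes a duplicate-run, 96-well arrayed viability screen: every plate
#' carries `controls_per_plate` wells transfected without siRNA (used for
#' on-plate normalization) and the remaining wells carry one library entry
#' each. Readout noise is multiplicative log-normal with coefficient of
#' variation `noise_cv` (viability readouts are positive and right-skewed),
#' and between-replicate concordance is induced by a shared per-gene latent
#' term with weight `replicate_correlation` on the log scale.
#'
#' @param n_genes Number of library genes (one siRNA pool per gene).
#' @param controls_per_plate Control (no-siRNA) wells per plate; default 11.
#' @param n_replicates Number of experimental replicates; default 2.
#' @param planted_hits Data frame with columns `gene_id` and `effect`
#'   (expected fold viability over the control mean, > 0), or `NULL`.
#' @param replicate_correlation Correlation of per-gene noise between
#'   replicates, in \[0, 1\]. Default 0.695, which reproduces a between-run
#'   z-score R^2 of about 0.483.
#' @param noise_cv Coefficient of variation of the multiplicative well noise.
#' @param control_mean Expected raw viability of a control well (a.u.).
#' @param seed Integer seed; recorded in the output's `seed` attribute.
#' @return A `screen_sim_config` list.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_genes,
                              controls_per_plate = 11,
                              n_replicates = 2,
                              planted_hits = NULL,
                              replicate_correlation = 0.695,
                              noise_cv = 0.2,
                              control_mean = 1000,
                              seed = NULL) {
  if (!is_count(n_genes)) {
    rlang::abort("`n_genes` must be a positive integer: the plate layout cannot cover an empty or fractional library.")
  }
  if (!is_count(controls_per_plate) || controls_per_plate >= 96) {
    rlang::abort("`controls_per_plate` must be an integer in [1, 95]: a 96-well plate needs at least one library well.")
  }
  if (!is_count(n_replicates)) rlang::abort("`n_replicates` must be a positive integer.")
  if (!is.null(planted_hits)) {
    planted_hits <- as_tibble(planted_hits)
    assert_columns(planted_hits, c("gene_id", "effect"), "`planted_hits`")
    if (any(planted_hits$effect <= 0)) rlang::abort("planted effects must be > 0")
  }
  if (!is.numeric(replicate_correlation) || replicate_correlation < 0 || replicate_correlation > 1) {
    rlang::abort("`replicate_correlation` must lie in [0, 1].")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) rlang::abort("`noise_cv` must be >= 0.")
  if (!is.numeric(control_mean) || control_mean <= 0) rlang::abort("`control_mean` must be > 0.")
  structure(
    list(
      n_genes = as.integer(n_genes),
      controls_per_plate = as.integer(controls_per_plate),
      n_replicates = as.integer(n_replicates),
      planted_hits = planted_hits,
      replicate_correlation = replicate_correlation,
      noise_cv = noise_cv,
      control_mean = control_mean,
      seed = seed
    ),
    class = "screen_sim_config"
  )
}

#' Simulate duplicate 96-well screen plates with known ground truth
#'
#' Lays the library out on 96-well plates (each plate holds
#' `96 - controls_per_plate` library wells plus the no-siRNA control wells;
#' the last plate may be underfilled but still carries its controls),
#' replicated `n_replicates` times with the same layout. Raw viability for a
#' gene well is `control_mean * effect * exp(noise)`, with log-normal noise
#' scaled so the expectation is exactly `effect * control_mean`; the per-gene
#' component of the noise is shared across replicates with weight
#' `replicate_correlation`.
#'
#' @param cfg A [screen_sim_config()].
#' @return A tibble with columns `plate`, `well`, `replicate`, `sirna_id`,
#'   `gene_id` (`NA` for control wells), `raw`, and a `role` column marking
#'   `"control"` vs `"gene"` wells. Attributes: `seed`, `planted_hits`.
#' @examples
#' plates <- simulate_screen(screen_sim_config(n_genes = 85, seed = 1))
#' dplyr::count(plates, plate, replicate, role)
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  genes_per_plate <- 96L - cfg$controls_per_plate
  n_plates <- ceiling(cfg$n_genes / genes_per_plate)

  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  effect <- rep(1, cfg$n_genes)
  if (!is.null(cfg$planted_hits)) {
    unknown <- setdiff(cfg$planted_hits$gene_id, gene_ids)
    if (length(unknown) > 0) {
      rlang::abort(sprintf("planted hit gene(s) not in library: %s",
                           paste(unknown, collapse = ", ")))
    }
    effect[match(cfg$planted_hits$gene_id, gene_ids)] <- cfg$planted_hits$effect
  }

  wells <- well_ids_96()
  control_wells <- wells[seq_len(cfg$controls_per_plate)]
  gene_wells <- setdiff(wells, control_wells)

  # log-normal noise with E[exp(noise)] = 1 and CV = noise_cv
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  rho <- cfg$replicate_correlation

  with_seed(cfg$seed, {
    latent <- rnorm(cfg$n_genes) # shared per-gene term across replicates
    out <- purrr::map_dfr(seq_len(cfg$n_replicates), function(rep_i) {
      plate_of_gene <- ((seq_len(cfg$n_genes) - 1L) %/% genes_per_plate) + 1L
      well_of_gene <- gene_wells[((seq_len(cfg$n_genes) - 1L) %% genes_per_plate) + 1L]
      eps <- rnorm(cfg$n_genes)
      z_noise <- sqrt(rho) * latent + sqrt(1 - rho) * eps
      gene_raw <- cfg$control_mean * effect *
        exp(sigma * z_noise - sigma^2 / 2)
      gene_rows <- tibble(
        plate = plate_of_gene,
        well = well_of_gene,
        replicate = rep_i,
        sirna_id = sprintf("si_%s", gene_ids),
        gene_id = gene_ids,
        role = "gene",
        raw = gene_raw
      )
      ctrl_rows <- tidyr::expand_grid(
        plate = seq_len(n_plates),
        well = control_wells
      )
      ctrl_rows <- dplyr::mutate(
        ctrl_rows,
        replicate = rep_i,
        sirna_id = "CONTROL",
        gene_id = NA_character_,
        role = "control",
        raw = cfg$control_mean * exp(sigma * rnorm(dplyr::n()) - sigma^2 / 2)
      )
      dplyr::arrange(dplyr::bind_rows(gene_rows, ctrl_rows),
                     .data$plate, .data$well)
    })
    attr(out, "seed") <- cfg$seed
    attr(out, "planted_hits") <- cfg$planted_hits
    out
  })
}
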