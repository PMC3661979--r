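#' Configuration for the synthetic immunofluorescence image generator
#'
#' Cells are disks with concentric disk nuclei (the simplest shapes with
#' exact ground-truth masks), placed without overlap and away from the image
#' border. Three registered channels are produced: a DNA (nuclear stain)
#' channel, a whole-cell channel and a target-protein channel whose
#' nuclear/cytoplasmic contrast is configurable. Gaussian pixel noise is
#' added to every channel and intensities are clamped at zero.
#'
#' @param image_size Integer length-2 vector (rows, cols) in pixels.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius,cell_radius Disk radii (px); `cell_radius` must
#'   exceed `nucleus_radius`.
#' @param nuclear_intensity,cytoplasmic_intensity Target-channel intensities
#'   (a.u.) inside the nucleus and in the cytoplasmic ring; their ratio is
#'   the per-cell ground truth.
#' @param background Additive background level in all channels (a.u.).
#' @param noise_sd Gaussian pixel noise standard deviation (a.u.).
#' @param dna_intensity,cell_intensity Foreground levels of the DNA and
#'   whole-cell channels (a.u.).
#' @param max_tries Placement attempts per cell before giving up.
#' @param seed Integer seed.
#' @return An `image_sim_config` list.
#' @export
image_sim_config <- function(image_size = c(256, 256),
                             n_cells = 8,
                             nucleus_radius = 6,
                             cell_radius = 14,
                             nuclear_intensity = 200,
                             cytoplasmic_intensity = 100,
                             background = 10,
                             noise_sd = 5,
                             dna_intensity = 180,
                             cell_intensity = 120,
                             max_tries = 2000,
                             seed = NULL) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            is_count(n_cells), nucleus_radius >= 1)
  if (cell_radius <= nucleus_radius) {
    rlang::abort("`cell_radius` must exceed `nucleus_radius`")
  }
  vals <- c(nuclear_intensity, cytoplasmic_intensity, background,
            dna_intensity, cell_intensity)
  if (any(vals < 0) || noise_sd < 0) rlang::abort("intensities and noise_sd must be >= 0")
  if (cytoplasmic_intensity == 0) rlang::abort("`cytoplasmic_intensity` must be > 0 (the N/C ratio is undefined otherwise)")
  structure(
    list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
         nucleus_radius = nucleus_radius, cell_radius = cell_radius,
         nuclear_intensity = nuclear_intensity,
         cytoplasmic_intensity = cytoplasmic_intensity,
         background = background, noise_sd = noise_sd,
         dna_intensity = dna_intensity, cell_intensity = cell_intensity,
         max_tries = as.integer(max_tries), seed = seed),
    class = "image_sim_config"
  )
}

#' Simulate a multi-channel cell image with known nuclear/cytoplasmic ratios
#'
#' @param cfg An [image_sim_config()].
#' @return List with numeric matrices `dna`, `cell`, `target` (equal
#'   dimensions, a.u. >= 0), label matrices `nucleus_mask` and `cell_mask`
#'   (0 = background, i = cell i), and `truth` (tibble `cell_id`, `row`,
#'   `col`, `ratio` with `ratio = nuclear_intensity / cytoplasmic_intensity`
#'   before noise).
#' @examples
#' img <- simulate_cell_image(image_sim_config(n_cells = 4, seed = 7))
#' img$truth
#' @export
simulate_cell_image <- function(cfg) {
  stopifnot(inherits(cfg, "image_sim_config"))
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  with_seed(cfg$seed, {
    margin <- cfg$cell_radius + 2
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < cfg$n_cells) {
      tries <- tries + 1
      if (tries > cfg$max_tries) {
        rlang::abort(sprintf(
          "could not place %d non-overlapping cells in %dx%d px after %d tries",
          cfg$n_cells, nr, nc, cfg$max_tries
        ))
      }
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >
              2 * cfg$cell_radius + 2)) {
        centers <- rbind(centers, cand)
      }
    }
    rows <- matrix(rep(seq_len(nr), nc), nrow = nr)
    cols <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
    nucleus_mask <- matrix(0L, nr, nc)
    cell_mask <- matrix(0L, nr, nc)
    for (i in seq_len(cfg$n_cells)) {
      d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
      cell_mask[d2 <= cfg$cell_radius^2] <- i
      nucleus_mask[d2 <= cfg$nucleus_radius^2] <- i
    }
    noisy <- function(base) {
      pmax(base + rnorm(nr * nc, sd = cfg$noise_sd), 0)
    }
    dna <- noisy(cfg$background + cfg$dna_intensity * (nucleus_mask > 0))
    cell <- noisy(cfg$background + cfg$cell_intensity * (cell_mask > 0))
    target <- noisy(cfg$background +
                      cfg$cytoplasmic_intensity * (cell_mask > 0 & nucleus_mask == 0) +
                      cfg$nuclear_intensity * (nucleus_mask > 0))
    truth <- tibble(
      cell_id = seq_len(cfg$n_cells),
      row = centers[, 1], col = centers[, 2],
      ratio = cfg$nuclear_intensity / cfg$cytoplasmic_intensity
    )
    list(dna = dna, cell = cell, target = target,
         nucleus_mask = nucleus_mask, cell_mask = cell_mask,
         truth = truth, seed = cfg$seed)
  })
}
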