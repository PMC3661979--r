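#' Run the full pipeline end-to-end on synthetic data
#'
#' Generates a synthetic screen, toy genome and cell images, runs every
#' analysis stage (normalization, Z-scores, dual-threshold hit calling,
#' exclusion ledger, validation; dedup, equal-depth subsampling, fold
#' filtering, densities, bin matrix, association scores, clustering, nearest
#' distances, rank enrichment; segmentation and N/C ratio comparison) and
#' writes all outputs plus a JSON provenance manifest into `out_dir`. The
#' run is fully determined by `seed`: identical seeds give identical output
#' checksums.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_genes Library size of the demo screen.
#' @param n_cells Cells per demo image group.
#' @return The manifest, invisibly (a list; also written to
#'   `manifest.json`). The manifest records inputs, parameters, seeds,
#'   output MD5 checksums and the filter-count ledger.
#' @export
run_demo <- function(out_dir = tempfile("pluriexit_demo"), seed = 1,
                     n_genes = 425, n_cells = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(screen = seed, genome = seed + 1000L, expr = seed + 2000L,
                image = seed + 3000L, subsample = seed + 4000L)
  filter_counts <- list()

  ## --- screen stage -------------------------------------------------------
  planted <- tibble(gene_id = sprintf("gene%05d", 1:3), effect = 5)
  scr_cfg <- screen_sim_config(n_genes = n_genes, planted_hits = planted,
                               seed = seeds$screen)
  plates <- simulate_screen(scr_cfg)
  write_screen_tsv(plates, file.path(out_dir, "screen_raw.tsv"))
  normalized <- normalize_plate(plates)
  z <- screen_zscores(normalized)
  hits <- call_hits(z)
  ledger <- apply_ledger(hits)
  readr::write_tsv(as_tibble(ledger), file.path(out_dir, "hit_ledger.tsv"),
                   progress = FALSE)
  filter_counts$screen <- attr(ledger, "provenance")

  ## --- chip stage ---------------------------------------------------------
  gen_cfg <- genome_sim_config(n_genes = 120, seed = seeds$genome)
  genome <- simulate_genome(gen_cfg)
  write_genes_bed(genome$genes, file.path(out_dir, "genes.bed"))
  for (f in names(genome$peaks)) {
    write_peaks_bed(genome$peaks[[f]],
                    file.path(out_dir, sprintf("peaks_%s.bed", f)))
  }
  deduped <- purrr::map(genome$reads, dedup_reads)
  equal <- subsample_equal(deduped, seed = seeds$subsample)
  filter_counts$reads <- list(
    n_raw = vapply(genome$reads, nrow, integer(1)),
    n_dedup = vapply(deduped, nrow, integer(1)),
    n_subsampled = vapply(equal, nrow, integer(1))
  )
  retained <- purrr::map(genome$peaks, filter_peaks, min_fold = 100)
  filter_counts$peaks <- list(
    n_called = vapply(genome$peaks, nrow, integer(1)),
    n_retained = vapply(retained, nrow, integer(1))
  )
  dens <- read_density(retained[[1]], equal[[names(retained)[1]]])
  readr::write_tsv(dens, file.path(out_dir, "peak_density.tsv"), progress = FALSE)
  bm <- build_bin_matrix(retained, genome$genes)
  assoc <- association_scores(retained, genome$genes)
  readr::write_tsv(assoc, file.path(out_dir, "association.tsv"), progress = FALSE)
  clustering <- cluster_profiles(bm)
  write_dendrogram_newick(clustering, file.path(out_dir, "factors.nwk"))
  nf <- nearest_factor_distance(retained[[1]],
                                dplyr::bind_rows(retained[-1]))
  readr::write_tsv(nf, file.path(out_dir, "nearest_factor.tsv"), progress = FALSE)
  bound <- bound_genes(assoc)
  ranked <- simulate_ranked_expression(genome$genes$gene_id,
                                       bound = bound[[1]], enrichment = 6,
                                       seed = seeds$expr)
  write_ranked_tsv(ranked, file.path(out_dir, "ranked_expression.tsv"))
  enr <- dplyr::bind_rows(
    rank_enrichment(ranked, bound[[1]], q = 0.02),
    rank_enrichment(ranked, bound[[1]], q = 0.05)
  )
  readr::write_tsv(enr, file.path(out_dir, "rank_enrichment.tsv"), progress = FALSE)

  ## --- imaging stage ------------------------------------------------------
  img_a <- simulate_cell_image(image_sim_config(
    image_size = c(384, 384), n_cells = n_cells,
    nuclear_intensity = 200, cytoplasmic_intensity = 100, seed = seeds$image))
  img_b <- simulate_cell_image(image_sim_config(
    image_size = c(384, 384), n_cells = n_cells,
    nuclear_intensity = 100, cytoplasmic_intensity = 100,
    seed = seeds$image + 1L))
  measure_one <- function(img) {
    masks <- segment_cells(img$dna, img$cell)
    measure_nc_ratio(masks, img$target)
  }
  ratios <- dplyr::bind_rows(
    dplyr::mutate(measure_one(img_a), group = "relocalized"),
    dplyr::mutate(measure_one(img_b), group = "control")
  )
  readr::write_tsv(ratios, file.path(out_dir, "cell_measurements.tsv"),
                   progress = FALSE)
  comparison <- compare_nc_groups(ratios)
  jsonlite::write_json(
    list(summary = tidy(comparison), test = glance(comparison)),
    file.path(out_dir, "nc_comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  ## --- manifest -----------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    pipeline = "pluriexit demo",
    version = as.character(utils::packageVersion("pluriexit")),
    seed = seed,
    stage_seeds = seeds,
    parameters = list(
      n_genes = n_genes, planted_hits = planted,
      z_hi = 3, z_lo = 2.5, min_fold = 100,
      window = 25000, bin = 1000, decay = 5000,
      n_cells = n_cells
    ),
    filter_counts = filter_counts,
    outputs = lapply(
      setNames(outputs, outputs),
      function(f) list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
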