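#' Configuration for the toy genome simulator
#'
#' Describes a small genome with evenly spaced gene models, per-factor peaks
#' placed at controlled summit-to-TSS distances, reads piled under peak
#' summits with a configurable fraction of exact PCR duplicates, and a
#' uniform IgG background.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param n_genes Total number of gene models (spread over chromosomes).
#' @param factors Character vector of factor names.
#' @param peaks_per_factor Peaks per factor.
#' @param planted_distances Summit-to-TSS offsets (bp, may be negative);
#'   recycled over peaks. All resulting coordinates must stay on-chromosome.
#' @param peak_width Peak interval width (bp); default 600, close to the
#'   typical width of high-confidence TF peaks.
#' @param reads_per_peak Reads sampled under each peak summit.
#' @param duplicate_fraction Fraction of each peak's reads that are exact
#'   copies (same chrom, start, strand) of another read; in \[0, 1).
#' @param igg_background_rate Expected IgG reads per bp (Poisson).
#' @param factor_offsets Integer rotation of the target-gene cycle per factor
#'   (recycled). The default `seq_along(factors) - 1` gives each factor a
#'   shifted set of target genes; all-zero offsets plant identical peak
#'   positions for every factor (perfectly co-bound factors).
#' @param gene_length Gene-body length (bp); default 2000.
#' @param seed Integer seed.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_chroms = 2,
                              chrom_length = 1e6,
                              n_genes = 40,
                              factors = c("Tfe3", "Oct4", "Sox2", "Nanog"),
                              peaks_per_factor = 20,
                              planted_distances = c(0, 1000, 5000, 10000),
                              peak_width = 600,
                              reads_per_peak = 100,
                              duplicate_fraction = 0.1,
                              igg_background_rate = 1e-4,
                              factor_offsets = seq_along(factors) - 1,
                              gene_length = 2000,
                              seed = NULL) {
  stopifnot(is_count(n_chroms), is_count(n_genes), is_count(peaks_per_factor),
            is_count(reads_per_peak), is_count(gene_length),
            is.character(factors), length(factors) >= 1,
            chrom_length > gene_length)
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    rlang::abort("`duplicate_fraction` must lie in [0, 1)")
  }
  if (igg_background_rate < 0) rlang::abort("`igg_background_rate` must be >= 0")
  if (max(abs(planted_distances)) >= chrom_length) {
    rlang::abort("planted distances exceed chromosome bounds")
  }
  structure(
    list(n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
         n_genes = as.integer(n_genes), factors = factors,
         peaks_per_factor = as.integer(peaks_per_factor),
         planted_distances = planted_distances, peak_width = peak_width,
         reads_per_peak = as.integer(reads_per_peak),
         duplicate_fraction = duplicate_fraction,
         igg_background_rate = igg_background_rate,
         factor_offsets = as.integer(rep_len(factor_offsets, length(factors))),
         gene_length = as.integer(gene_length), seed = seed),
    class = "genome_sim_config"
  )
}

#' Simulate a toy genome with genes, factor peaks, reads and IgG background
#'
#' Gene models are spread evenly over the chromosomes with alternating
#' strands; the TSS is `start` on `+` and `end - 1` on `-`. For each factor,
#' peak summits are placed at the planted offsets from the TSSs of cycled
#' target genes; the peak interval is the summit padded to `peak_width`.
#' Reads per peak are drawn without replacement from a +/-150 bp offset pool
#' around the summit with Gaussian weights (so a duplicate fraction of zero
#' guarantees a duplicate-free read set), then the requested fraction of
#' exact duplicates is injected. IgG reads are uniform over the genome at
#' `igg_background_rate` per bp.
#'
#' @param cfg A [genome_sim_config()].
#' @return List with `genes` (gene tibble incl. `tss`), `peaks` (named list
#'   of peak tibbles with `summit`, `fold_enrichment`), `reads` (named list
#'   of read tibbles, one per factor plus `"IgG"`), and `truth` (tibble of
#'   planted factor, peak, gene, distance).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  with_seed(cfg$seed, {
    genes <- sim_gene_models(cfg)
    half <- floor(cfg$peak_width / 2)
    peak_sets <- list()
    read_sets <- list()
    truth <- list()
    for (fi in seq_along(cfg$factors)) {
      f <- cfg$factors[fi]
      idx <- seq_len(cfg$peaks_per_factor)
      target <- genes[((idx - 1L + cfg$factor_offsets[fi]) %% nrow(genes)) + 1L, ]
      offset <- cfg$planted_distances[((idx - 1L) %% length(cfg$planted_distances)) + 1L]
      summit <- target$tss + offset
      if (any(summit - half < 0 | summit + half > cfg$chrom_length)) {
        rlang::abort("planted peak extends beyond chromosome bounds; reduce distances or enlarge chrom_length")
      }
      pk <- tibble(
        chrom = target$chrom,
        start = summit - half,
        end = summit - half + cfg$peak_width,
        name = sprintf("%s_peak%03d", f, idx),
        score = 0,
        strand = ".",
        summit = summit,
        fold_enrichment = exp(rnorm(length(idx), mean = log(200), sd = 0.4))
      )
      peak_sets[[f]] <- pk
      read_sets[[f]] <- sim_peak_reads(pk, cfg)
      truth[[f]] <- tibble(factor = f, peak = pk$name, gene_id = target$gene_id,
                           distance = abs(summit - target$tss))
    }
    n_igg <- rpois(1, cfg$igg_background_rate * cfg$chrom_length * cfg$n_chroms)
    read_sets[["IgG"]] <- if (n_igg == 0) {
      tibble(chrom = character(), start = numeric(), strand = character())
    } else {
      tibble(
        chrom = sprintf("chr%d", sample.int(cfg$n_chroms, n_igg, replace = TRUE)),
        start = floor(runif(n_igg, 0, cfg$chrom_length)),
        strand = sample(c("+", "-"), n_igg, replace = TRUE)
      ) |> dplyr::arrange(.data$chrom, .data$start)
    }
    list(genes = genes, peaks = peak_sets, reads = read_sets,
         truth = dplyr::bind_rows(truth), seed = cfg$seed)
  })
}

sim_gene_models <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  genes <- tidyr::expand_grid(chrom_i = seq_len(cfg$n_chroms),
                              slot = seq_len(per_chrom)) |>
    head(cfg$n_genes)
  spacing <- floor(cfg$chrom_length / (per_chrom + 1))
  if (spacing <= cfg$gene_length) {
    rlang::abort("gene models do not fit: increase chrom_length or reduce n_genes")
  }
  genes |>
    dplyr::mutate(
      gene_id = sprintf("g%03d", dplyr::row_number()),
      chrom = sprintf("chr%d", .data$chrom_i),
      start = .data$slot * spacing,
      end = .data$start + cfg$gene_length,
      strand = ifelse(dplyr::row_number() %% 2 == 1, "+", "-"),
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1)
    ) |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "tss")
}

# Reads under each summit: distinct (offset, strand) draws weighted by a
# Gaussian profile, plus the configured fraction of exact copies.
sim_peak_reads <- function(pk, cfg) {
  pool_offsets <- -150:150
  w <- dnorm(pool_offsets, 0, 60)
  pool <- tidyr::expand_grid(offset = pool_offsets, strand = c("+", "-"))
  pool_w <- rep(w, each = 2)
  n_dup <- round(cfg$duplicate_fraction * cfg$reads_per_peak)
  n_base <- cfg$reads_per_peak - n_dup
  if (n_base > nrow(pool)) {
    rlang::abort("reads_per_peak too large for the distinct-position pool (max 602 unique reads/peak)")
  }
  reads <- purrr::pmap_dfr(list(pk$chrom, pk$summit), function(cm, s) {
    picked <- pool[sample.int(nrow(pool), n_base, prob = pool_w), ]
    base <- tibble(chrom = cm, start = s + picked$offset, strand = picked$strand)
    if (n_dup > 0) {
      base <- dplyr::bind_rows(
        base, base[sample.int(n_base, n_dup, replace = TRUE), ]
      )
    }
    base
  })
  dplyr::arrange(reads, .data$chrom, .data$start, .data$strand)
}

#' Simulate a ranked differential-expression table with planted enrichment
#'
#' Orders a gene universe by weighted sampling without replacement
#' (Plackett-Luce): genes in `bound` carry weight `enrichment`, all others
#' weight 1, so `enrichment = 1` yields an exchangeable (uniform) ranking
#' and large values push every bound gene ahead of every unbound one.
#'
#' @param gene_ids Character vector: the ranked universe.
#' @param bound Character subset to over-represent at the top.
#' @param enrichment Sampling-weight ratio, >= 1.
#' @param seed Integer seed.
#' @return Tibble with `rank` and `gene_id`, ordered by rank.
#' @export
simulate_ranked_expression <- function(gene_ids, bound = character(),
                                       enrichment = 1, seed = NULL) {
  if (length(gene_ids) == 0) rlang::abort("empty gene universe")
  if (anyDuplicated(gene_ids)) rlang::abort("gene ids must be unique")
  stray <- setdiff(bound, gene_ids)
  if (length(stray) > 0) rlang::abort("`bound` must be a subset of `gene_ids`")
  if (enrichment < 1) rlang::abort("`enrichment` must be >= 1")
  w <- ifelse(gene_ids %in% bound, enrichment, 1)
  with_seed(seed, {
    ord <- sample.int(length(gene_ids), prob = w)
    tibble(rank = seq_along(gene_ids), gene_id = gene_ids[ord])
  })
}
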