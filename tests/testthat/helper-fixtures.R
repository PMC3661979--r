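# Small in-code fixtures and brute-force oracles shared across test files.

make_reads <- function(chrom, start, strand = "+") {
  tibble::tibble(chrom = chrom, start = start,
                 strand = rep_len(strand, length(start)))
}

make_peaks <- function(chrom, start, end, summit = NULL, fold = 200) {
  tibble::tibble(
    chrom = chrom, start = start, end = end,
    name = sprintf("p%02d", seq_along(start)), score = 0, strand = ".",
    summit = if (is.null(summit)) floor((start + end) / 2) else summit,
    fold_enrichment = rep_len(fold, length(start))
  )
}

make_genes <- function(chrom, start, end, strand = "+") {
  n <- length(start)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = rep_len(chrom, n),
    start = start, end = end, strand = rep_len(strand, n),
    tss = ifelse(rep_len(strand, n) == "+", start, end - 1)
  )
}

random_reads <- function(n, n_chrom = 2, max_pos = 1000) {
  make_reads(
    chrom = sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE),
    start = sample.int(max_pos, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# O(n*m) reference for read counting in peaks
naive_peak_counts <- function(peaks, reads) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(reads$chrom == peaks$chrom[i] &
          reads$start >= peaks$start[i] & reads$start < peaks$end[i])
  }, numeric(1))
}

# all-pairs reference for nearest summit distances
naive_nearest <- function(query, other) {
  vapply(seq_len(nrow(query)), function(i) {
    d <- abs(other$summit[other$chrom == query$chrom[i]] - query$summit[i])
    if (length(d) == 0) NA_real_ else min(d)
  }, numeric(1))
}

# per-bin overlap scan reference for the binary bin matrix
naive_bin_row <- function(peaks, bins) {
  vapply(seq_len(nrow(bins)), function(i) {
    any(peaks$chrom == bins$chrom[i] &
          peaks$start < bins$end[i] & peaks$end > bins$start[i])
  }, logical(1)) * 1L
}

# a small noiseless two-channel image pair via the simulator
noiseless_image <- function(n_cells = 5, nuclear = 200, cytoplasmic = 100,
                            seed = 11) {
  simulate_cell_image(image_sim_config(
    image_size = c(256, 256), n_cells = n_cells,
    nuclear_intensity = nuclear, cytoplasmic_intensity = cytoplasmic,
    background = 0, noise_sd = 0, seed = seed
  ))
}
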