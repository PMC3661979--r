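---
title: "Models and methods behind the pluriexit pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pluriexit pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluriexit)
```

`pluriexit` packages the computation behind a genome-scale siRNA screen for
genes whose knockdown blocks the exit from naive pluripotency, together
with the ChIP-seq association analysis and the automated image
quantification used in the follow-up. This vignette is the package's
account of the models it implements, the parameters that matter, the
choices made where the method was genuinely open, and what the synthetic
generators do and do not emulate.

## Screen model

Each 96-well plate carries 11 wells transfected without siRNA. Raw
viability (an Alamar-Blue-type readout, arbitrary units, strictly
non-negative) is normalized per plate and run by dividing by the mean of
these on-plate controls (`normalize_plate()`). Division — percent of
control — is used rather than subtraction because it preserves positivity
and makes the result invariant to plate-level intensity scaling; that
invariance is asserted as a property test (multiplying any one plate's raw
values by an arbitrary constant leaves all downstream Z-scores unchanged to
1e-12).

Within each run, gene-level normalized values are standardized across the
library (`screen_zscores()`): `z = (x − mean) / sd` with the sample (n−1)
standard deviation and control wells excluded. With thousands of genes the
n vs n−1 choice is numerically immaterial, but it is fixed for
reproducibility. Library entries (siRNA pools) are scored individually;
where a gene has duplicated entries, gene-level collapse keeps the entry
with the largest `min(z1, z2)` — the entry closest to passing — and this is
the only aggregation applied.

A gene is **screen positive** (`call_hits()`) when `max(z1, z2) > z_hi` and
`min(z1, z2) > z_lo`, defaults 3 and 2.5. The thresholds are applied
order-agnostically because the screen design does not privilege either run;
the stricter ordered reading (run 1 must exceed 3) is available via
`order_agnostic = FALSE`. Genes missing a replicate are flagged unscorable
and excluded with a warning, never imputed.

### The false-positive bound

For a null gene with independent standard-normal Z-scores in the two runs,

$$P(\text{positive}) = 2\,Q(z_{hi})\,Q(z_{lo}) - Q(z_{hi})^2,$$

with $Q$ the upper normal tail; at the defaults this is
$1.494\times10^{-5}$, far below the 1% level the dual thresholds were
designed to guarantee. `false_positive_probability()` evaluates this closed
form, a bivariate-normal variant for correlated runs (orthant probabilities
by one-dimensional quadrature against the conditional tail, `integrate()`
at `rel.tol = 1e-12`), and a Monte-Carlo mode used as an independent
cross-check in the tests.

### A calibration subtlety

The closed form assumes the null Z-scores are normal. The synthetic screen
deliberately uses multiplicative log-normal readout noise (viability
readouts are positive and right-skewed), and a log-normal standardized on
the raw scale has a heavier-than-normal upper tail: at 10⁵ null genes the
raw-scale pipeline produces measurably more dual-threshold passes than the
normal-theory bound predicts. This is a real property of the method, not a
bug: any screen whose readout noise is right-skewed will exceed the
normal-tail bound at stringent thresholds. `screen_zscores(transform =
"log")` standardizes log-viability instead, under which the generator's
null is exactly normal and the full pipeline calibrates to the closed form
(asserted at 10⁵ genes in the acceptance suite). The raw-scale default is
kept because it is the conventional screen calculation; the log option is
the statistically safer choice when the readout is believed log-normal.

### Ledger and validation

`apply_ledger()` intersects screen positives with an expressed-gene set and
removes manual exclusions; `primary_hit = screen_positive ∧ expressed ∧
¬manual_excluded`, with counts at every step kept as provenance (the
bookkeeping identity — positives = primary + expression-excluded +
manual-excluded for disjoint exclusion subsets — is tested).
`call_validation()` marks a gene validated when at least `min_sirnas = 2`
individually retested siRNAs increase viability more than `fold = 2`-fold
over control; the comparison is strict (`> 2`), so a fold change of exactly
2 does not validate.

## ChIP-seq downstream analysis

All intervals are BED-convention: 0-based starts, half-open `[start, end)`;
strand affects only the TSS (start on `+`, `end − 1` on `−`). Malformed
coordinates are hard errors naming file and line, never clamped.

* `dedup_reads()` keeps one read per (chrom, start, strand) — the standard
  PCR-duplicate heuristic for single-end data; it is idempotent.
* `subsample_equal()` draws `min(sizes)` reads uniformly without
  replacement from every sample, including IgG, so depths match before any
  comparison; one seed per invocation.
* `filter_peaks()` retains peaks with fold enrichment over IgG of at least
  `min_fold = 100`; the boundary is inclusive ("at least 100-fold").
* `read_density()` counts read starts inside each peak and scales by peak
  width in kb. Counting is binary search on per-chromosome sorted starts,
  so the O(n·m) scan used as a test oracle stays independent.

### Association score and bin matrix

The association of a factor with a gene (`association_scores()`) is
$S = \sum_i e^{-d_i/\lambda}$ over the factor's peak summits, with $d_i$
the summit-to-TSS distance and decay length $\lambda$ = 5 kb. Only peaks
whose summit lies within `window` = 25 kb of the anchor are summed: a peak
at the window edge contributes at most $e^{-5} \approx 0.0067$, so the
truncation is numerically negligible while keeping the computation local; a
`global = TRUE` switch sums all same-chromosome peaks for exactness. Two
window anchors are provided because "±25 kb of any gene" can mean the TSS
or the gene body: `anchor = "tss"` (default, consistent with the
TSS-anchored distance in the score) and `anchor = "gene"` (gene body ±
window; the distance itself is still summit-to-TSS). A gene is *bound* by a
factor when at least one peak qualifies — peak presence, not a score
threshold, so a single distal peak with a small score still marks binding.

`build_bin_matrix()` tiles `[gene_start − 25 kb, gene_end + 25 kb)` into
1-kb bins (union over genes, duplicate bins collapsed) and sets a factor's
bin to 1 when any retained peak interval overlaps the bin — overlap of the
interval, not summit containment, because "binding site in this bin" reads
most naturally as occupancy. The half-open overlap test is `peak_start <
bin_end ∧ peak_end > bin_start`; a peak spanning a bin boundary marks both
bins.

### Clustering, distances, enrichment

`cluster_profiles()` clusters factor rows with `1 − Pearson r` as the
distance and **average linkage** — the distance is part of the method, the
linkage was open, and average linkage is the least committal of the
standard choices for correlation distances. Zero-variance rows cannot be
correlated and are dropped with a warning rather than silently assigned a
distance. The dendrogram exports to Newick via `ape`.

`nearest_factor_distance()` reports, per query summit, the minimal absolute
distance to another factor's summits on the same chromosome, `NA` when the
chromosome is absent — never infinity, so downstream summaries fail loudly
rather than averaging infinities.

`rank_enrichment()` takes the top `floor(q·N)` genes of a ranked table
(`q` = 0.02 or 0.05 conventionally), computes the bound-gene enrichment
over the genome-wide fraction, and a **hypergeometric upper-tail** p-value.
The statistic behind this kind of top-slice enrichment was an open choice;
the hypergeometric is the exact null for "at least k bound genes in a
random slice of n from N" and is cross-checked in the tests against full
enumeration (the 20-gene example equals 155/4845 exactly) and against a
10⁵-shuffle permutation null. Note the hypergeometric p-values are
discrete, hence super-uniform under the null — a literal
Kolmogorov–Smirnov uniformity check over simulation seeds rejects even when
the null holds, so the generator's exchangeability is instead verified by a
goodness-of-fit of top-slice counts against the exact hypergeometric pmf.

## Image quantification

`segment_cells()` follows the standard CellProfiler-style recipe: global
Otsu threshold on the DNA channel, connected components, a minimum-area
filter (`min_area` = 20 px, small enough for the synthetic nuclei and large
enough to reject noise specks), then Voronoi-style propagation of the
nucleus seeds over the thresholded cell channel to assign cell bodies
(`EBImage::propagate`). Cells touching the image border are excluded
because a truncated cytoplasm biases the ratio; nuclei are clipped to their
own cell so containment is exact. All parameters used are recorded in the
returned object.

`measure_nc_ratio()` computes, per cell, the mean target intensity over the
nucleus and over the cytoplasm (cell minus nucleus) and their ratio. The
ratio is invariant to rescaling the whole target channel; a uniform channel
gives exactly 1. Cells with an empty cytoplasm mask are dropped with a
warning rather than producing a division by zero.

`compare_nc_groups()` reports five-number box-whisker summaries (whiskers
at 1.5×IQR — the convention was unstated upstream, so the Tukey default is
used and recorded) and a two-sided two-sample **Student's** t-test (pooled
variance) on the per-cell ratios, with Welch's correction behind
`var_equal = FALSE`. Cells are pooled across images and the per-group n is
reported; treating pooled cells as independent observations overstates
degrees of freedom when images are the true experimental unit — users with
image-level structure should aggregate per image first.

## Synthetic generators

The generators define the package's study conditions; they are first-class
tested code, not fixtures.

* **Screen** (`simulate_screen()`): 96-well plates, 11 control wells each
  (85 library wells; the last plate may be underfilled but keeps its
  controls), two replicates by default. Noise is multiplicative log-normal
  with CV `noise_cv` = 0.2 — a realistic dispersion for plate-reader
  viability assays — mean-corrected so a planted effect of 5 gives expected
  raw viability exactly 5× the control mean. Between-replicate concordance
  comes from a shared per-gene latent term with weight
  `replicate_correlation` = 0.695 on the log scale, chosen so the
  between-run Z-score R² is near 0.483, the concordance a duplicate screen
  of this type reports. What it does **not** model: plate-position
  (edge/row) effects, siRNA off-target structure, batch drift — so passing
  tests show the pipeline's arithmetic and calibration are right, not that
  it is robust to those artifacts (deliberately so: plate-effect correction
  is out of scope).
* **Genome** (`simulate_genome()`): evenly spaced 2-kb gene models with
  alternating strands on 1-Mb chromosomes; per factor, peak summits planted
  at configured TSS offsets of cycled target genes (a per-factor rotation
  makes factors distinct; all-zero rotations create perfectly co-bound
  factor pairs for clustering tests). Peak intervals default to 600 bp,
  the typical width of high-confidence TF peaks. Reads are drawn without
  replacement from a ±150 bp Gaussian-weighted offset pool around each
  summit — so with `duplicate_fraction = 0` the read set is duplicate-free
  by construction — and exact duplicates are then injected at the
  configured fraction; IgG reads are uniform Poisson background. No
  sequences, no alignment errors, no chromatin-accessibility structure.
* **Ranked expression** (`simulate_ranked_expression()`): weighted
  sampling without replacement (Plackett–Luce), bound genes at weight
  `enrichment`; weight 1 gives exchangeable ranks, large weights push all
  bound genes to the top.
* **Images** (`simulate_cell_image()`): non-overlapping disk cells with
  concentric disk nuclei — the simplest geometry with exact ground-truth
  masks — Gaussian pixel noise, intensities clamped at zero. Ground-truth
  N/C ratio is `nuclear_intensity / cytoplasmic_intensity` before
  background and noise; with a nonzero common background the measurable
  ratio is compressed toward 1, which the noisy-recovery tests therefore
  run at zero background. No point-spread function, no intensity gradients,
  no touching cells — so segmentation robustness to clumping is untested.

Every generator draws from one seeded RNG per call (the caller's RNG state
is restored) and records its seed; identical seeds give byte-identical
outputs, which the end-to-end demo (`run_demo()`) turns into identical
output checksums in its provenance manifest.

## Numerical and edge-case policy

* Degenerate runs (zero dispersion across genes) are errors, not NaN
  propagation; plates without controls or with non-positive control means
  are errors naming the plate.
* Closed-form association values are asserted to 6 decimals; plate-scale
  invariance to 1e-12; noiseless image ratios to 2% (mask-boundary pixels);
  noisy median ratios to 10% of truth.
* Problem sizes in the test suite: 10⁵ genes for null calibration, 10⁷
  Monte-Carlo draws for the false-positive bound, 2,000-gene screens with
  0.75% planted hits for recovery (matching the rare-hit regime of a real
  genome-scale screen — planting many strong hits inflates the across-gene
  sd and lowers everyone's Z, a screen-design fact worth remembering),
  ≤10⁵-bp toy genomes for brute-force oracle equivalence, and ~50 noisy
  cells for ratio recovery.

## Known limitations

* No plate-effect correction (B-score/median polish), no MAD-robust
  Z-score variant, no off-target deconvolution.
* Peak calling, read alignment and motif discovery are out of scope; the
  pipeline consumes aligned-read and called-peak files.
* The hypergeometric enrichment treats the bound set as fixed; it does not
  model correlation between binding and expression rank beyond membership.
* Segmentation is tuned to well-separated cells; densely packed or
  overlapping cells would need seeded watershed on distance transforms and
  are not modeled by the generator either.
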