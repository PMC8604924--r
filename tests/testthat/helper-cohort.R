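# shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

# small planted cohort taken through the profile stages
small_cohort <- function() memo("small", function() {
  cfg <- cohort_config(n_samples = 60, n_chromosomes = 1,
                       chrom_length = 10e6, n_rtqtls = 3, seed = 101)
  co <- simulate_cohort(cfg)
  filtered <- filter_points_per_sample(filter_windows_global(co$depth))
  smoothed <- normalize_and_smooth(filtered)
  list(config = cfg, cohort = co, filtered = filtered, smoothed = smoothed)
})

# planted cohort with full rtQTL mapping (used by signal/multi/chromatin
# tests); kept modest so mapping stays fast
mapped_cohort <- function() memo("mapped", function() {
  cfg <- cohort_config(n_samples = 100, n_chromosomes = 2,
                       chrom_length = 10e6, n_rtqtls = 5, seed = 5)
  co <- simulate_cohort(cfg)
  filtered <- filter_points_per_sample(filter_windows_global(co$depth))
  smoothed <- normalize_and_smooth(filtered)
  mapped <- map_rtqtls(smoothed, filtered, co$genotypes,
                       n_perm = 200, perm_cap = 1000, seed = 5)
  peaks <- call_peak_clusters(smoothed)
  valleys <- call_peak_clusters(smoothed, what = "minima")
  list(config = cfg, cohort = co, filtered = filtered, smoothed = smoothed,
       mapped = mapped, peaks = peaks, valleys = valleys)
})

# helper to build an rt_matrix directly from a value matrix
toy_matrix <- function(values, window_size = 10000, state = "raw") {
  grid <- rt_grid(1, ncol(values) * window_size, window_size)
  rt_matrix(values, grid, state = state)
}

# deterministic genotype table from a dosage matrix
toy_genotypes <- function(dosage, spacing = 10000, chrom = "chr1") {
  info <- tibble::tibble(
    variant_id = sprintf("t%03d", seq_len(ncol(dosage))),
    chrom = chrom, pos = spacing * seq_len(ncol(dosage)),
    ref = "A", alt = "G")
  genotype_table(dosage, info)
}
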