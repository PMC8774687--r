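# Shared fixtures, built once per test run and memoised. Simulation scales are
# deliberately small (miniature pseudo-genomes, bin-level draws) so the whole
# suite stays within minutes on one CPU; the acceptance tests state their own
# scales explicitly.

# expand a masked-length vector back to the full grid with NA padding
`%thru%` <- function(vals, mask) {
  out <- rep(NA_real_, length(mask)); out[mask] <- vals; out
}

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# 5-pair toy alignment fixture with one MAPQ-0 pair and one duplicate-start
# pair: 3 pairs survive the four filters (hand enumeration).
toy_pairs_df <- function() {
  data.frame(
    qname = c("p1", "p2", "p3", "p4", "p5"),
    chrom = "chr1",
    start1 = c(1000, 2000, 3000, 1000, 5000),   # p4 repeats p1's start
    start2 = c(1173, 2160, 3150, 1210, 5170),
    mapq1 = c(30, 0, 30, 30, 30),               # p2 fails MAPQ
    mapq2 = c(30, 30, 30, 30, 30),
    stringsAsFactors = FALSE
  )
}

# Small case/control cohort: 8 pseudo-chromosomes x 40 bins at 750 kb,
# 0.25x-equivalent coverage, ff = 7.5%, whole-chr8 gain. Used for power,
# specificity and fetal-fraction properties.
fx_small_params <- function(...) {
  sim_params(grid = sim_grid(n_chrom = 8, chrom_length = 30e6, bin_size = 750e3),
             n_controls = 20, n_cases = 1, ff = 0.075, seed = 101, ...)
}

fx_small_cohort <- function() fixture("small_cohort", function() {
  simulate_cohort(fx_small_params())
})

fx_small_ref <- function() fixture("small_ref", function() {
  build_reference_set(fx_small_cohort()$panel, K = 100, n_comp = 5)
})

# Score a freshly simulated sample against the small reference.
fx_scored_sample <- function(is_case, ff, seed, combine = "fisher") {
  p <- fx_small_params()
  s <- simulate_sample(p, is_case = is_case, ff = ff, seed = seed,
                       profiles = fx_small_cohort()$profiles)
  score_sample(s, fx_small_ref(), combine = combine)
}

# Null-calibration cohort: 11 chromosomes x 200 bins (2200 bins) at reduced
# coverage, K = 300. Controls for the reference and held-out negatives for
# scoring are disjoint.
fx_null_params <- function() {
  sim_params(grid = sim_grid(n_chrom = 11, chrom_length = 150e6, bin_size = 750e3),
             n_controls = 16, n_cases = 0, coverage = 800, ff = 0.075,
             seed = 202)
}

fx_null_ref <- function() fixture("null_ref", function() {
  build_reference_set(simulate_cohort(fx_null_params())$panel, K = 300, n_comp = 5)
})
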