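# Shared scaled-default cohort fixture; simulated once per test run.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- simulate_cohort(scaled_default_config())
  }
  .cohort_cache$cohort
}

default_results <- function() {
  if (is.null(.cohort_cache$results)) {
    .cohort_cache$results <- analyze_cohort(default_cohort())
  }
  .cohort_cache$results
}

# a tiny genome frame used across unit tests
tiny_index <- function() genome_index(c("A", "B"), c(200000, 120000))

# build a window table directly (for ROH rule tests): het per window given
# as counts over 50-kb windows on one chromosome
window_fixture <- function(n_het, missing_prop = 0, size = 50000,
                           chrom = "A") {
  n <- length(n_het)
  data.table::data.table(
    chrom = chrom, start = (seq_len(n) - 1) * size, end = seq_len(n) * size,
    window_len = size, n_het = n_het,
    n_missing = round(missing_prop * size),
    het = n_het / size,
    missing_prop = rep(missing_prop, length.out = n)
  )
}
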