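# shared fixtures built in code; the 50-sample cohort is cached per test run
.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- simulate_cohort(
      cohort_config(n_tumors = 40, n_cell_lines = 10, seed = 101))
  }
  .cohort_cache$cohort
}

test_analysis <- function() {
  if (is.null(.cohort_cache$analysis)) {
    .cohort_cache$analysis <- analyze_cohort(test_cohort())
  }
  .cohort_cache$analysis
}

# minimal variant tibble builder
make_variants <- function(n = 0, ...) {
  base <- tibble::tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), somatic_score = numeric(),
    consequence = character(), gene = character(),
    population_af = numeric(), verified = character())
  if (n == 0) return(base)
  defaults <- list(sample_id = "S1", chrom = "chr1", pos = seq_len(n),
                   ref = "A", alt = "C", somatic_score = 10,
                   consequence = "missense", gene = "G",
                   population_af = NA_real_, verified = "untested")
  args <- utils::modifyList(defaults, list(...))
  do.call(tibble::tibble, args)
}
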