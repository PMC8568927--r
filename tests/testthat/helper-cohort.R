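# Shared fixtures: all synthetic data is generated in code at test time.

small_genome <- function(chroms = c("chr1", "chr2", "chr3")) {
  genome_model(chroms = chroms)
}

# Six independent primaries (A-F), C seeding five metastases (G-K) through a
# 667-variant trunk: the archetypal multifocal patient, noise off so counts
# are exact.
patient1_config <- function(seed = 101, trunk = 667,
                            private_range = c(300, 1700), ...) {
  sim_config(
    n_primaries = 6, metastatic_primary_ids = "C", n_mets_per_seed = 5,
    trunk_sizes = trunk, private_range = private_range,
    noise = FALSE, indel_rate = 0, seed = seed, ...
  )
}

# A compact noise-free cohort for fast unit tests.
tiny_cohort <- function(seed = 7, ...) {
  simulate_cohort(sim_config(
    n_primaries = 3, metastatic_primary_ids = "C", n_mets_per_seed = 2,
    trunk_sizes = 50, private_range = c(20, 40), genome = small_genome(),
    noise = FALSE, indel_rate = 0, purity = 1, seed = seed, ...
  ))
}

# Random strict-filter call table exercising every rule.
random_call_table <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    depth = rpois(n, 40) + 1L,
    alt_fwd = rbinom(n, 10, 0.5),
    alt_rev = rbinom(n, 10, 0.5),
    normal_depth = rpois(n, 30),
    in_normal = runif(n) < 0.1,
    caller_set = sample(c("mutect2,varscan", "varscan"), n, TRUE, c(0.8, 0.2))
  ) |>
    dplyr::mutate(
      alt_fwd = pmin(.data$alt_fwd, .data$depth %/% 2),
      alt_rev = pmin(.data$alt_rev, .data$depth - .data$alt_fwd),
      vaf = (.data$alt_fwd + .data$alt_rev) / .data$depth
    )
}
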