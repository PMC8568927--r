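flat_windows <- function(n = 200, chrom = "chr1", lambda = 800, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1L) * 2000L,
    end = seq_len(n) * 2000L,
    count_normal = rpois(n, lambda),
    count_T = rpois(n, lambda)
  )
}

test_that("a flat genome yields one neutral segment per chromosome", {
  win <- dplyr::bind_rows(flat_windows(chrom = "chr1", seed = 1),
                          flat_windows(chrom = "chr2", seed = 2))
  seg <- segment_logratio(win, "count_T")
  expect_equal(nrow(seg), 2)
  expect_true(all(seg$state == "neutral"))
  # segmentation conservation: segments tile each chromosome
  expect_equal(seg$start, c(0, 0))
  expect_equal(seg$end, c(400000, 400000))
})

test_that("hemizygous loss at purity 0.6 recovers the closed-form log ratio", {
  coh <- simulate_cohort(sim_config(
    n_primaries = 1, metastatic_primary_ids = character(0),
    n_mets_per_seed = 0, trunk_sizes = numeric(0), private_range = c(5, 5),
    genome = small_genome(c("chr1", "chr17", "chr18")), purity = 0.6,
    cna_events = list(truth_cna("chr18", "loss", "A", carriers = "A")),
    indel_rate = 0, seed = 31
  ))
  seg <- segment_logratio(coh$windows, "count_A")
  loss <- seg[seg$chrom == "chr18", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$state, "loss")
  expect_lt(abs(loss$log2_ratio - log2(0.7)), 0.05)
  expect_true(all(seg$state[seg$chrom != "chr18"] == "neutral"))
})

test_that("a single step breakpoint is recovered within two windows", {
  n <- 300
  bp_window <- 180 # truth: loss starts here
  set.seed(4)
  win <- tibble::tibble(
    chrom = "chr5",
    start = (seq_len(n) - 1L) * 2000L,
    end = seq_len(n) * 2000L,
    count_normal = rpois(n, 800),
    count_T = rpois(n, 800 * c(rep(1, bp_window), rep(0.7, n - bp_window)))
  )
  seg <- segment_logratio(win, "count_T")
  expect_equal(nrow(seg), 2)
  found <- seg$start[2] / 2000
  expect_lte(abs(found - bp_window), 2)
  expect_equal(seg$state, c("neutral", "loss"))
})

test_that("window-grid violations and missing columns are input errors", {
  win <- flat_windows(20)
  expect_error(segment_logratio(win, "count_missing"),
               class = "mfclone_input_error")
  bad <- win
  bad$start[5] <- bad$start[4] # overlap
  expect_error(segment_logratio(bad, "count_T"),
               class = "mfclone_input_error")
})

test_that("whole-chromosome calls require 90% single-state coverage", {
  seg <- tibble::tibble(
    chrom = "chr18", start = c(0, 95000), end = c(95000, 100000),
    n_windows = c(95, 5), log2_ratio = c(-0.5, 0),
    state = c("loss", "neutral")
  )
  ev <- call_whole_chrom(seg, 100000)
  expect_equal(ev$kind, "loss")
  expect_equal(ev$covered_fraction, 0.95)
  focal <- tibble::tibble(
    chrom = "chr1", start = c(0, 10000), end = c(10000, 100000),
    n_windows = c(10, 90), log2_ratio = c(-0.5, 0),
    state = c("loss", "neutral")
  )
  expect_equal(nrow(call_whole_chrom(focal, 100000)), 0)
})

test_that("configured whole-chromosome losses are all detected across a cohort", {
  n_samples <- 61
  carriers <- mfclone:::make_sample_ids(n_samples)[seq_len(32)]
  coh <- simulate_cohort(sim_config(
    n_primaries = n_samples, metastatic_primary_ids = character(0),
    n_mets_per_seed = 0, trunk_sizes = numeric(0), private_range = c(2, 4),
    genome = small_genome(c("chr17", "chr18")), purity = 0.6,
    cna_events = list(truth_cna("chr18", "loss", "A", carriers = carriers)),
    indel_rate = 0, seed = 61
  ))
  gm <- coh$config$genome$chromosomes
  len <- gm$length[gm$chrom == "chr18"]
  hits <- vapply(coh$samples$sample[coh$samples$role != "blood_normal"],
                 function(s) {
    seg <- segment_logratio(coh$windows, paste0("count_", s))
    nrow(call_whole_chrom(seg[seg$chrom == "chr18", ], len)) > 0
  }, logical(1))
  expect_equal(sum(hits), 32L)
  expect_setequal(names(hits)[hits], carriers)
})

test_that("chromothripsis rule fires on two-state oscillation only", {
  osc <- tibble::tibble(
    chrom = "chr13", start = (0:19) * 1e5, end = (1:20) * 1e5,
    n_windows = 50, log2_ratio = rep(c(-0.5, 0), 10),
    state = rep(c("loss", "neutral"), 10)
  )
  call <- detect_chromothripsis(osc)
  expect_true(call$positive)
  expect_equal(call$oscillation_fraction, 1)
  expect_equal(call$n_state_switches, 19)

  flat <- osc[1, ]
  expect_false(detect_chromothripsis(flat)$positive)

  set.seed(99)
  messy <- tibble::tibble(
    chrom = "chr13", start = (0:11) * 1e5, end = (1:12) * 1e5,
    n_windows = 50, log2_ratio = 0,
    state = c("loss", "neutral", "gain", "loss", "loss", "gain",
              "neutral", "neutral", "gain", "loss", "gain", "neutral")
  )
  mc <- detect_chromothripsis(messy)
  expect_false(mc$positive)
  expect_lt(mc$two_state_fraction, 0.9)
})

test_that("oscillating copy number survives segmentation end to end", {
  # alternating loss/neutral blocks of 30 windows across a chromosome
  n_blocks <- 14
  per <- 30
  n <- n_blocks * per
  set.seed(17)
  ratio <- rep(rep(c(0.6, 1), length.out = n_blocks), each = per)
  win <- tibble::tibble(
    chrom = "chr13", start = (seq_len(n) - 1L) * 2000L,
    end = seq_len(n) * 2000L,
    count_normal = rpois(n, 800), count_T = rpois(n, 800 * ratio)
  )
  seg <- segment_logratio(win, "count_T")
  call <- detect_chromothripsis(seg)
  expect_true(call$positive)
  expect_gte(call$n_segments, 10)
})

test_that("the small-segment reporting filter drops sub-25kb segments", {
  seg <- tibble::tibble(
    chrom = "chr1", start = c(0, 30000, 50000), end = c(30000, 50000, 90000),
    n_windows = c(15, 10, 20), log2_ratio = 0, state = "neutral"
  )
  expect_equal(nrow(filter_small_segments(seg)), 2)
})
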