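# Closed-form het-SNP VAF generator for a monoallelic event at purity p.
sim_phase_snps <- function(n_snps, p_ref, p_test, same_homolog, depth = 40,
                           test_biallelic = FALSE, seed = 1) {
  set.seed(seed)
  alt_on_lost_ref <- runif(n_snps) < 0.5
  alt_on_lost_test <- if (same_homolog) alt_on_lost_ref else !alt_on_lost_ref
  vaf_expect <- function(p, on_lost) {
    ifelse(on_lost, (1 - p) / (2 - p), 1 / (2 - p))
  }
  draw <- function(mu) {
    d <- rpois(n_snps, depth)
    rbinom(n_snps, d, mu) / pmax(d, 1)
  }
  tibble::tibble(
    chrom = "chr18", pos = seq_len(n_snps) * 1000L,
    vaf_normal = draw(rep(0.5, n_snps)),
    vaf_R = draw(vaf_expect(p_ref, alt_on_lost_ref)),
    vaf_T = if (test_biallelic) draw(rep(0.5, n_snps)) else
      draw(vaf_expect(p_test, alt_on_lost_test))
  )
}

test_that("same-homolog loss in both samples is called same_as_reference", {
  snps <- sim_phase_snps(200, 0.6, 0.6, same_homolog = TRUE, seed = 2)
  pc <- phase_event(snps, "R", "T")
  expect_equal(pc$homolog_call, "same_as_reference")
  expect_gte(pc$concordance_fraction, 0.9)
  # VAFs concentrate near the closed-form 1/(2-p) and (1-p)/(2-p)
  hi <- snps$vaf_R[snps$vaf_R > 0.5]
  expect_lt(abs(mean(hi) - 1 / 1.4), 0.03)
})

test_that("opposite-homolog loss is called different_from_reference", {
  snps <- sim_phase_snps(200, 0.6, 0.5, same_homolog = FALSE, seed = 3)
  pc <- phase_event(snps, "R", "T")
  expect_equal(pc$homolog_call, "different_from_reference")
  expect_lte(pc$concordance_fraction, 0.1)
})

test_that("balanced test VAFs despite copy loss are called biallelic", {
  snps <- sim_phase_snps(200, 0.6, 0.6, TRUE, test_biallelic = TRUE, seed = 4)
  pc <- phase_event(snps, "R", "T")
  expect_equal(pc$homolog_call, "biallelic")
})

test_that("too few informative SNPs yields indeterminate with a reason", {
  snps <- sim_phase_snps(10, 0.6, 0.6, TRUE, seed = 5)
  pc <- phase_event(snps, "R", "T")
  expect_equal(pc$homolog_call, "indeterminate")
  expect_match(pc$reason, "informative")
  expect_error(phase_event(snps[, 1:2], "R", "T"),
               class = "mfclone_input_error")
})

test_that("phasing recovers the true homolog relation in nearly all simulated patients", {
  set.seed(77)
  n_pat <- 100
  correct <- 0L
  informative <- 0L
  for (i in seq_len(n_pat)) {
    same <- runif(1) < 0.5
    snps <- sim_phase_snps(
      120, runif(1, 0.4, 0.9), runif(1, 0.4, 0.9), same,
      depth = 40, seed = 7000 + i
    )
    pc <- phase_event(snps, "R", "T")
    if (pc$homolog_call %in% c("same_as_reference", "different_from_reference")) {
      informative <- informative + 1L
      truth <- if (same) "same_as_reference" else "different_from_reference"
      if (pc$homolog_call == truth) correct <- correct + 1L
    }
  }
  expect_gte(informative, 90)
  expect_gte(correct / informative, 0.98)
})

test_that("the exact binomial tail matches enumeration and worked examples", {
  expect_equal(concordance_binomial_test(1, 1)$p_value, 0.5)
  expect_equal(concordance_binomial_test(13, 13)$p_value, 0.5^13)
  expect_equal(concordance_binomial_test(10, 12)$p_value,
               sum(choose(12, 10:12)) / 2^12)
  for (n in c(3, 7, 12)) {
    for (k in c(0, 1, n %/% 2, n)) {
      expect_equal(concordance_binomial_test(k, n)$p_value,
                   enumerate_binomial_tail(k, n))
    }
  }
  expect_error(concordance_binomial_test(1, 0), class = "mfclone_input_error")
  expect_error(concordance_binomial_test(5, 3), class = "mfclone_input_error")
})

test_that("purity is twice the median clonal VAF, clipped and flagged", {
  expect_equal(estimate_purity(rep(0.5, 30))$purity, 1)
  set.seed(6)
  d <- rpois(200, 40)
  v <- rbinom(200, d, 0.3) / pmax(d, 1)
  est <- estimate_purity(v)
  expect_lt(abs(est$purity - 0.6), 0.05)
  expect_false(est$flagged)
  low <- estimate_purity(rep(0.125, 25))
  expect_true(low$flagged)
  expect_error(estimate_purity(rep(0.3, 5)), class = "mfclone_input_error")
})
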