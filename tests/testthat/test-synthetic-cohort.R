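test_that("draw_mutations handles the empty case and rejects unknown signatures", {
  out <- draw_mutations(0, c(SBS5 = 1))
  expect_equal(nrow(out), 0)
  expect_named(out, c("chrom", "pos", "ref", "alt", "context", "channel"))
  expect_error(draw_mutations(5, c(NOPE = 1)), class = "mfclone_config_error")
})

test_that("pure-signature draws follow the 96-channel distribution", {
  sigs <- synthetic_signature_matrix()
  set.seed(11)
  muts <- draw_mutations(10000, c(SBS5 = 1), signatures = sigs)
  expect_equal(nrow(muts), 10000)
  expect_equal(anyDuplicated(paste(muts$chrom, muts$pos)), 0)
  counts <- table(factor(muts$channel, levels = rownames(sigs)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = sigs[, "SBS5"]))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort simulation is deterministic and conserves lineage counts", {
  cfg <- sim_config(
    n_primaries = 3, metastatic_primary_ids = "B", n_mets_per_seed = 2,
    trunk_sizes = 40, private_range = c(10, 20), genome = small_genome(),
    embryonic_shared = list(list(samples = c("A", "B"), count = 5)),
    contamination = list(list(donor = "A", recipient = "C", count = 7,
                              trace_vaf = c(0.02, 0.05))),
    indel_rate = 0, seed = 99
  )
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$het_snps, c2$het_snps)
  expect_identical(c1$windows, c2$windows)

  # conservation: one truth row per configured variant
  n_priv <- sum(table(c1$truth$variants$lineage_id[
    c1$truth$variants$lineage == "private"
  ]))
  expect_equal(nrow(c1$truth$variants), 40 + n_priv + 5 + 7)
  # lineage exclusivity: a variant key appears exactly once in the truth
  expect_equal(anyDuplicated(
    paste(c1$truth$variants$chrom, c1$truth$variants$pos)
  ), 0)
  counts <- table(c1$truth$variants$lineage)
  expect_equal(unname(counts[["trunk"]]), 40)
  expect_equal(unname(counts[["embryonic"]]), 5)
  expect_equal(unname(counts[["contamination"]]), 7)
})

test_that("invalid configurations are refused", {
  expect_error(
    sim_config(n_primaries = 3, metastatic_primary_ids = "Z"),
    class = "mfclone_config_error"
  )
  expect_error(sim_config(purity = 1.2), class = "mfclone_config_error")
  expect_error(sim_config(purity = 0), class = "mfclone_config_error")
  expect_error(sim_config(private_range = c(10, 5)),
               class = "mfclone_config_error")
  expect_error(
    sim_config(cna_events = list(truth_cna("chr99", "loss", carriers = "A"))),
    class = "mfclone_config_error"
  )
})

test_that("a mutation-free sample yields an empty call table but het SNPs", {
  coh <- simulate_cohort(sim_config(
    n_primaries = 1, metastatic_primary_ids = character(0),
    n_mets_per_seed = 0, trunk_sizes = numeric(0),
    private_range = c(0, 0), genome = small_genome("chr22"),
    indel_rate = 0, noise = FALSE, seed = 5
  ))
  expect_equal(nrow(coh$calls), 0)
  expect_gt(nrow(coh$het_snps), 0)
})

test_that("metastases inherit their seed's trunk and observed VAFs track purity", {
  coh <- tiny_cohort()
  truth <- coh$truth
  trunk_keys <- with(
    truth$variants[truth$variants$lineage == "trunk", ],
    paste(chrom, pos, ref, alt, sep = ":")
  )
  for (s in c("C", "D", "E")) {
    keys_s <- with(coh$calls[coh$calls$sample == s, ],
                   paste(chrom, pos, ref, alt, sep = ":"))
    expect_true(all(trunk_keys %in% keys_s))
  }
  expect_false(any(trunk_keys %in% with(
    coh$calls[coh$calls$sample == "A", ],
    paste(chrom, pos, ref, alt, sep = ":")
  )))

  # noise on: mean observed VAF of a clonal diploid variant ~ purity/2
  cohn <- simulate_cohort(sim_config(
    n_primaries = 1, metastatic_primary_ids = character(0),
    n_mets_per_seed = 0, trunk_sizes = numeric(0),
    private_range = c(300, 300), genome = small_genome(),
    purity = 0.6, depth = 40, indel_rate = 0, noise = TRUE, seed = 21
  ))
  v <- cohn$calls$vaf
  expect_gt(length(v), 200)
  # Monte-Carlo band: SE of the mean of ~300 binomial VAFs at depth 40
  se <- sqrt(0.3 * 0.7 / 40) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.3), 5 * se + 0.01) # small upward bias from the 2-read floor
})

test_that("het-SNP VAFs on a monoallelic loss follow the purity mixture law", {
  p <- 0.6
  coh <- simulate_cohort(sim_config(
    n_primaries = 1, metastatic_primary_ids = character(0),
    n_mets_per_seed = 0, trunk_sizes = numeric(0), private_range = c(5, 5),
    genome = small_genome("chr18"), purity = p, noise = FALSE,
    cna_events = list(truth_cna("chr18", "loss", "A", carriers = "A")),
    indel_rate = 0, seed = 13
  ))
  vals <- sort(unique(round(coh$het_snps$vaf_A, 10)))
  expect_equal(vals, sort(round(c((1 - p) / (2 - p), 1 / (2 - p)), 10)))
  # both homologs are represented among SNPs
  expect_gt(sum(coh$het_snps$vaf_A > 0.5), 10)
  expect_gt(sum(coh$het_snps$vaf_A < 0.5), 10)
})

test_that("cohorts round-trip through disk including VCF emission", {
  skip_if_not_installed("vcfR")
  coh <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_calls(file.path(dir, "calls_A.tsv"))
  orig <- dplyr::select(dplyr::filter(coh$calls, sample == "A"), -sample)
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$pos, orig$pos)
  vcf <- read_calls(file.path(dir, "calls_A.vcf"))
  expect_equal(nrow(vcf), nrow(orig))
  expect_equal(sort(vcf$pos), sort(orig$pos))
  expect_equal(vcf$alt_fwd + vcf$alt_rev,
               orig$alt_fwd[match(paste(vcf$chrom, vcf$pos),
                                  paste(orig$chrom, orig$pos))] +
                 orig$alt_rev[match(paste(vcf$chrom, vcf$pos),
                                    paste(orig$chrom, orig$pos))])
})
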