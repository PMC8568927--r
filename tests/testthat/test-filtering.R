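clean_call <- function(n = 1) {
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 100L, ref = "C", alt = "T",
    vaf = 0.3, depth = 40L, alt_fwd = 6L, alt_rev = 6L,
    normal_depth = 30L, in_normal = FALSE,
    caller_set = "mutect2,varscan", variant_type = "SNV"
  )
}

test_that("each strict rule rejects its own violation and clean calls pass", {
  bad <- clean_call(6)
  bad$pos <- 1000L + seq_len(6) * 50L
  bad$normal_depth[1] <- 19L          # normal coverage
  bad$alt_rev[2] <- 0L                # strand
  bad$in_normal[3] <- TRUE            # present in normal
  bad$vaf[4] <- 0.005                 # min VAF
  bad$caller_set[5] <- "varscan"      # caller intersection
  # row 6 blacklisted
  blk <- paste("chr1", bad$pos[6], "C", "T", sep = ":")
  calls <- dplyr::bind_rows(clean_call(4), bad)
  out <- apply_strict_filters(calls, filter_config(blacklist = blk))
  expect_equal(nrow(out), 4)
  expect_equal(out$pos, clean_call(4)$pos)
  rej <- filter_rejections(out)
  expect_equal(nrow(rej), 6)
  expect_setequal(
    rej$rule,
    c("normal_coverage", "strand", "in_normal", "min_vaf",
      "caller_intersection", "blacklist")
  )
})

test_that("normal coverage of 19 reads fails the >= 20 contract", {
  x <- clean_call()
  x$normal_depth <- 19L
  out <- apply_strict_filters(x)
  expect_equal(nrow(out), 0)
  expect_equal(filter_rejections(out)$rule, "normal_coverage")
  x$normal_depth <- 20L
  expect_equal(nrow(apply_strict_filters(x)), 1)
})

test_that("empty input, malformed records and SNVs near indels are handled", {
  expect_equal(nrow(apply_strict_filters(clean_call(0))), 0)
  bad <- clean_call()
  bad$vaf <- 1.5
  expect_error(apply_strict_filters(bad), class = "mfclone_input_error")

  x <- dplyr::bind_rows(clean_call(2), clean_call(1))
  x$sample <- "A"
  x$variant_type[3] <- "indel"
  x$pos <- c(100L, 5000L, 102L) # SNV at 100 is 2 bp from the indel
  out <- apply_strict_filters(x)
  expect_equal(nrow(out), 2) # the far SNV and the indel itself survive
  expect_equal(filter_rejections(out)$rule, "indel_proximity")
})

test_that("filtering is idempotent and monotone in each threshold", {
  for (seed in 1:5) {
    calls <- random_call_table(120, seed)
    base_cfg <- filter_config()
    out1 <- apply_strict_filters(calls, base_cfg)
    out2 <- apply_strict_filters(out1, base_cfg)
    expect_equal(nrow(out2), nrow(out1))
    expect_equal(out2$pos, out1$pos)

    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
    tighter <- list(
      filter_config(min_normal_depth = 35),
      filter_config(min_alt_reads = 6),
      filter_config(min_vaf = 0.2)
    )
    for (cfg in tighter) {
      expect_true(all(key(apply_strict_filters(calls, cfg)) %in% key(out1)))
    }
  }
})

test_that("whitelist recall recovers low-support shared variants but not singletons", {
  expect_equal(nrow(whitelist_recall(character(0), clean_call(3))), 0)

  relaxed <- dplyr::bind_rows(
    dplyr::mutate(clean_call(3), sample = "donor"),
    dplyr::mutate(clean_call(3), sample = "recipient",
                  vaf = 0.04, alt_fwd = c(2L, 1L, 0L), alt_rev = 0L)
  )
  wl <- pair_whitelist(clean_call(3), clean_call(0))
  rec <- whitelist_recall(wl, relaxed)
  # donor keeps all 3; recipient only the variant with >= 2 supporting reads
  expect_equal(sum(rec$sample == "donor"), 3)
  expect_equal(sum(rec$sample == "recipient"), 1)
  expect_equal(rec$pos[rec$sample == "recipient"], 100L)

  expect_error(whitelist_recall("chr1-100", relaxed),
               class = "mfclone_input_error")
})

test_that("strict calls are a subset of their own sample's recall", {
  for (seed in 6:9) {
    calls <- random_call_table(150, seed)
    calls$sample <- sample(c("A", "B"), nrow(calls), replace = TRUE)
    strict <- apply_strict_filters(calls)
    sa <- strict[strict$sample == "A", ]
    sb <- strict[strict$sample == "B", ]
    if (nrow(sa) == 0 || nrow(sb) == 0) next
    rec <- whitelist_recall(pair_whitelist(sa, sb), calls)
    key <- function(x) paste(x$sample, x$chrom, x$pos, x$ref, x$alt)
    expect_true(all(key(sa) %in% key(rec)))
    expect_true(all(key(sb) %in% key(rec)))
  }
})
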