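test_that("Fitch score matches the brute-force assignment oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    mat <- random_character_matrix(n - 1, sample(5:12, 1))
    phy <- ape::rtree(n, tip.label = sample(rownames(mat)))
    expect_equal(fitch_score(phy, mat), brute_fitch_score(phy, mat))
  }
})

test_that("Fitch score agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (i in 1:20) {
    mat <- random_character_matrix(5, 15)
    phy <- ape::rtree(6, tip.label = sample(rownames(mat)))
    pd <- phangorn::phyDat(mat, type = "USER", levels = c(0, 1))
    expect_equal(fitch_score(phy, mat),
                 as.numeric(phangorn::parsimony(phy, pd, method = "fitch")))
  }
})

test_that("degenerate matrices score as expected", {
  mat <- random_character_matrix(4, 6)
  zero <- mat
  zero[, ] <- 0L
  phy <- ape::rtree(5, tip.label = rownames(mat))
  expect_equal(fitch_score(phy, zero), 0)
  # perfect phylogeny: nested carrier sets change exactly once per column
  pp <- rbind(
    s1 = c(1, 1, 0, 0, 0), s2 = c(1, 0, 1, 0, 0), s3 = c(0, 0, 0, 1, 1),
    s4 = c(0, 0, 0, 1, 0), normal = c(0, 0, 0, 0, 0)
  )
  storage.mode(pp) <- "integer"
  attr(pp, "outgroup") <- "normal"
  colnames(pp) <- paste0("chr1:", 1:5, ":C:T")
  mp <- search_mp_tree(pp)
  expect_equal(mp$score, ncol(pp))
})

test_that("exhaustive search attains the brute-force minimum over topologies", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  for (i in 1:25) {
    mat <- random_character_matrix(sample(4:5, 1), sample(6:10, 1))
    pd <- phangorn::phyDat(mat, type = "USER", levels = c(0, 1))
    all_topo <- phangorn::allTrees(nrow(mat), tip.label = rownames(mat))
    oracle <- min(vapply(all_topo, function(tr) {
      as.numeric(phangorn::parsimony(tr, pd, method = "fitch"))
    }, numeric(1)))
    expect_equal(search_mp_tree(mat)$score, oracle)
  }
})

test_that("heuristic search matches the exhaustive optimum on small matrices", {
  set.seed(19)
  for (i in 1:15) {
    mat <- random_character_matrix(5, 10)
    exact <- search_mp_tree(mat, exhaustive_max = 9)
    heur <- search_mp_tree(mat, exhaustive_max = 0)
    expect_equal(heur$score, exact$score)
  }
})

test_that("results are invariant to sample relabeling order", {
  coh <- tiny_cohort()
  f <- apply_strict_filters(coh$calls)
  mat <- build_character_matrix(f)
  mp1 <- search_mp_tree(mat)
  perm <- mat[sample(nrow(mat)), , drop = FALSE]
  attr(perm, "outgroup") <- "normal"
  mp2 <- search_mp_tree(perm)
  expect_equal(mp1$score, mp2$score)
  expect_equal(
    ape::dist.topo(ape::unroot(mp1$phy), ape::unroot(mp2$phy))[1], 0
  )
})

test_that("noise-free simulations recover the seeding structure", {
  set.seed(123)
  n_ok <- 0
  n_runs <- 25
  for (i in 1:n_runs) {
    cfg <- sim_config(
      n_primaries = 3, metastatic_primary_ids = sample(c("A", "B", "C"), 1),
      n_mets_per_seed = 2, trunk_sizes = sample(50:200, 1),
      private_range = c(20, 60), genome = small_genome(),
      noise = FALSE, indel_rate = 0, seed = 1000 + i
    )
    coh <- simulate_cohort(cfg)
    mat <- build_character_matrix(apply_strict_filters(coh$calls))
    mp <- search_mp_tree(mat)
    clade <- sort(c(cfg$metastatic_primary_ids, coh$truth$tree$sample))
    found <- any(vapply((length(mp$phy$tip.label) + 1):(length(mp$phy$tip.label) + mp$phy$Nnode),
                        function(nd) {
                          identical(sort(mfclone:::tips_below(mp$phy, nd)), clade)
                        }, logical(1)))
    if (found) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, n_runs)
})

test_that("branch counts place the trunk on the metastatic clade", {
  coh <- tiny_cohort()
  mat <- build_character_matrix(apply_strict_filters(coh$calls))
  mp <- assign_branch_counts(search_mp_tree(mat), mat)
  # homoplasy-free matrix: counts conserve columns
  expect_equal(sum(mp$edge_counts), ncol(mat))
  expect_equal(sum(mp$edge_counts), mp$score)
  # the branch subtending {C, D, E} carries exactly the 50 trunk variants
  phy <- mp$phy
  ntip <- length(phy$tip.label)
  trunk_edge <- which(vapply(seq_len(nrow(phy$edge)), function(k) {
    identical(sort(mfclone:::tips_below(phy, phy$edge[k, 2])),
              c("C", "D", "E"))
  }, logical(1)))
  expect_equal(mp$edge_counts[trunk_edge], 50)
})

test_that("an all-private matrix puts every count on terminal branches", {
  mat <- rbind(
    s1 = c(1, 1, 0, 0, 0), s2 = c(0, 0, 1, 1, 0), s3 = c(0, 0, 0, 0, 1),
    normal = c(0, 0, 0, 0, 0)
  )
  storage.mode(mat) <- "integer"
  colnames(mat) <- paste0("chr1:", 1:5, ":C:T")
  attr(mat, "outgroup") <- "normal"
  mp <- assign_branch_counts(search_mp_tree(mat), mat)
  phy <- mp$phy
  ntip <- length(phy$tip.label)
  internal <- phy$edge[, 2] > ntip
  expect_true(all(mp$edge_counts[internal] == 0))
  tip_counts <- setNames(mp$edge_counts[!internal],
                         phy$tip.label[phy$edge[!internal, 2]])
  expect_equal(tip_counts[c("s1", "s2", "s3", "normal")],
               c(s1 = 2, s2 = 2, s3 = 1, normal = 0))
})

test_that("homoplastic columns are counted once per reconstructed change", {
  # carriers {A, B} on a tree grouping A with C: two changes, both placed
  mat <- rbind(
    A = c(1, 1, 1, 0), C = c(1, 1, 0, 1), B = c(0, 0, 1, 1),
    normal = c(0, 0, 0, 0)
  )
  storage.mode(mat) <- "integer"
  colnames(mat) <- paste0("chr1:", 1:4, ":C:T")
  attr(mat, "outgroup") <- "normal"
  mp <- search_mp_tree(mat)
  mp <- assign_branch_counts(mp, mat)
  # brute-force oracle: parsimony length of each column sums to total counts
  expect_equal(sum(mp$edge_counts), brute_fitch_score(mp$phy, mat))
})

test_that("bootstrap support is high for strong trunks, low without signal, monotone between", {
  coh <- tiny_cohort() # 50-variant trunk for {C, D, E}
  mat <- build_character_matrix(apply_strict_filters(coh$calls))
  bs <- bootstrap_support(mat, n_reps = 200, seed = 5)
  trunk <- bs$support$support[bs$support$clade == "C|D|E"]
  expect_gte(trunk, 98)
  # identical seed reproduces supports
  bs2 <- bootstrap_support(mat, n_reps = 200, seed = 5)
  expect_equal(bs$support, bs2$support)

  # star matrix: every resolution equally good, supports < 50
  star <- rbind(
    s1 = c(1, 0, 0, 0), s2 = c(0, 1, 0, 0), s3 = c(0, 0, 1, 0),
    s4 = c(0, 0, 0, 1), normal = c(0, 0, 0, 0)
  )
  storage.mode(star) <- "integer"
  colnames(star) <- paste0("chr1:", 1:4, ":C:T")
  attr(star, "outgroup") <- "normal"
  bstar <- bootstrap_support(star, n_reps = 200, seed = 5)
  expect_true(all(bstar$support$support < 50))

  # weak trunk lands strictly between no-signal and strong-signal support
  weak <- simulate_cohort(sim_config(
    n_primaries = 3, metastatic_primary_ids = "C", n_mets_per_seed = 2,
    trunk_sizes = 3, private_range = c(30, 40), genome = small_genome(),
    noise = FALSE, indel_rate = 0, purity = 1, seed = 8
  ))
  wmat <- build_character_matrix(apply_strict_filters(weak$calls))
  bw <- bootstrap_support(wmat, n_reps = 200, seed = 5)
  wtrunk <- bw$support$support[bw$support$clade == "C|D|E"]
  expect_gt(wtrunk, max(bstar$support$support))
  expect_lt(wtrunk, trunk)

  expect_error(bootstrap_support(mat, n_reps = 0),
               class = "mfclone_config_error")
})
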