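# Independent brute-force oracles, deliberately naive and separate from the
# package's Fitch implementation.

# Minimum state changes for one binary column on a fixed topology, by
# exhaustive enumeration of internal-node state assignments.
brute_column_changes <- function(phy, x) {
  ntip <- length(phy$tip.label)
  nn <- phy$Nnode
  combos <- as.matrix(expand.grid(rep(list(0:1), nn)))
  tip_states <- as.integer(x[phy$tip.label])
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    st <- c(tip_states, combos[i, ])
    changes <- sum(st[phy$edge[, 1]] != st[phy$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

brute_fitch_score <- function(phy, mat) {
  sum(vapply(seq_len(ncol(mat)), function(j) {
    brute_column_changes(phy, setNames(mat[, j], rownames(mat)))
  }, numeric(1)))
}

# Random binary matrix with no all-zero columns and an all-zero outgroup row.
random_character_matrix <- function(n_samples, n_cols, p = 0.5) {
  repeat {
    m <- matrix(rbinom(n_samples * n_cols, 1, p), n_samples, n_cols)
    if (all(colSums(m) > 0)) break
  }
  m <- rbind(m, 0L)
  rownames(m) <- c(paste0("s", seq_len(n_samples)), "normal")
  storage.mode(m) <- "integer"
  attr(m, "outgroup") <- "normal"
  m
}

# One-sided binomial tail by exhaustive outcome enumeration (n <= 12).
enumerate_binomial_tail <- function(k, n, p0 = 0.5) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  succ <- rowSums(outcomes)
  prob <- p0^succ * (1 - p0)^(n - succ)
  sum(prob[succ >= k])
}
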