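# ---- internal unrooted-tree representation ---------------------------------
# A `utree` is an undirected edge list over integer node ids with named tip
# labels; tips have degree 1, internal nodes degree 3 (one trifurcation acts
# as the unrooted "root"). This keeps stepwise addition, NNI and Fitch
# scoring allocation-light during tree search and bootstrapping.

utree3 <- function(labels) {
  stopifnot(length(labels) == 3)
  list(
    edge = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
    tip_label = setNames(labels, 1:3),
    next_id = 5L
  )
}

attach_tip <- function(ut, edge_row, label) {
  w <- ut$next_id
  t <- ut$next_id + 1L
  u <- ut$edge[edge_row, 1]
  v <- ut$edge[edge_row, 2]
  list(
    edge = rbind(ut$edge[-edge_row, , drop = FALSE],
                 c(u, w), c(w, v), c(w, t)),
    tip_label = c(ut$tip_label, setNames(label, t)),
    next_id = t + 1L
  )
}

ut_adjacency <- function(ut) {
  nmax <- ut$next_id - 1L
  adj <- vector("list", nmax)
  for (k in seq_len(nrow(ut$edge))) {
    a <- ut$edge[k, 1]; b <- ut$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Preorder node list and parent vector from a DFS rooted at `root`.
ut_dfs <- function(ut, root) {
  adj <- ut_adjacency(ut)
  nmax <- ut$next_id - 1L
  parent <- integer(nmax)
  po <- integer(nmax)
  stack <- root
  parent[root] <- 0L
  cnt <- 0L
  while (length(stack) > 0) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    cnt <- cnt + 1L
    po[cnt] <- node
    for (nb in adj[[node]]) {
      if (nb != parent[node]) {
        parent[nb] <- node
        stack <- c(stack, nb)
      }
    }
  }
  list(preorder = po[seq_len(cnt)], parent = parent)
}

# Fitch small-parsimony length over weighted column patterns.
# `states`: tips x patterns matrix of 1 ({0}) / 2 ({1}), rows named by label.
fitch_ut <- function(ut, states, weights) {
  tip_ids <- as.integer(names(ut$tip_label))
  is_tip <- rep(FALSE, ut$next_id - 1L)
  is_tip[tip_ids] <- TRUE
  root <- which(!is_tip)[1]
  dfs <- ut_dfs(ut, root)
  P <- length(weights)
  S <- matrix(0L, ut$next_id - 1L, P)
  S[tip_ids, ] <- states[ut$tip_label[as.character(tip_ids)], , drop = FALSE]
  changes <- numeric(P)
  for (node in rev(dfs$preorder)) {
    p <- dfs$parent[node]
    if (p == 0L) next
    child <- S[node, ]
    acc <- S[p, ]
    if (acc[1] == 0L) {
      S[p, ] <- child
    } else {
      inter <- bitwAnd(acc, child)
      z <- inter == 0L
      if (any(z)) {
        changes[z] <- changes[z] + 1
        inter[z] <- acc[z] + child[z] # disjoint union: {0}+{1} = {0,1}
      }
      S[p, ] <- inter
    }
  }
  sum(changes * weights)
}

# All NNI rearrangements of an unrooted binary utree.
ut_nni_neighbors <- function(ut) {
  tip_ids <- as.integer(names(ut$tip_label))
  is_tip <- rep(FALSE, ut$next_id - 1L)
  is_tip[tip_ids] <- TRUE
  out <- list()
  find_row <- function(edge, a, b) {
    which((edge[, 1] == a & edge[, 2] == b) | (edge[, 1] == b & edge[, 2] == a))
  }
  for (k in seq_len(nrow(ut$edge))) {
    u <- ut$edge[k, 1]; v <- ut$edge[k, 2]
    if (is_tip[u] || is_tip[v]) next
    nb_u <- setdiff(c(ut$edge[ut$edge[, 1] == u, 2], ut$edge[ut$edge[, 2] == u, 1]), v)
    nb_v <- setdiff(c(ut$edge[ut$edge[, 1] == v, 2], ut$edge[ut$edge[, 2] == v, 1]), u)
    b <- nb_u[2]
    for (cc in nb_v) {
      e <- ut$edge
      e[find_row(e, u, b), ] <- c(u, cc)
      e[find_row(e, v, cc), ] <- c(v, b)
      out[[length(out) + 1]] <- list(edge = e, tip_label = ut$tip_label,
                                     next_id = ut$next_id)
    }
  }
  out
}

# Canonical rooted newick: root between the outgroup tip and the rest,
# children sorted lexicographically at every node.
ut_canonical_newick <- function(ut, outgroup) {
  tip_ids <- as.integer(names(ut$tip_label))
  og_id <- tip_ids[ut$tip_label == outgroup]
  adj <- ut_adjacency(ut)
  is_tip <- rep(FALSE, ut$next_id - 1L)
  is_tip[tip_ids] <- TRUE
  sub <- function(node, from) {
    if (is_tip[node]) return(ut$tip_label[[as.character(node)]])
    kids <- setdiff(adj[[node]], from)
    paste0("(", paste(sort(vapply(kids, sub, character(1), from = node)),
                      collapse = ","), ")")
  }
  v <- adj[[og_id]][1]
  paste0("(", outgroup, ",", sub(v, og_id), ");")
}

# Unrooted splits as sorted label keys for the side not containing `outgroup`;
# only non-trivial splits (>= 2 labels on each side) are returned.
ut_splits <- function(ut, outgroup) {
  tip_ids <- as.integer(names(ut$tip_label))
  og_id <- tip_ids[ut$tip_label == outgroup]
  dfs <- ut_dfs(ut, og_id)
  nmax <- ut$next_id - 1L
  below <- vector("list", nmax)
  is_tip <- rep(FALSE, nmax)
  is_tip[tip_ids] <- TRUE
  for (node in rev(dfs$preorder)) {
    if (is_tip[node]) below[[node]] <- ut$tip_label[[as.character(node)]]
    p <- dfs$parent[node]
    if (p > 0L) below[[p]] <- c(below[[p]], below[[node]])
  }
  n_tip <- length(tip_ids)
  keys <- character(0)
  for (node in dfs$preorder) {
    if (is_tip[node] || dfs$parent[node] == 0L) next
    labs <- below[[node]]
    if (length(labs) >= 2 && length(labs) <= n_tip - 2) {
      keys <- c(keys, paste(sort(labs), collapse = "|"))
    }
  }
  unique(keys)
}

# Collapse a binary matrix to unique column patterns with weights.
collapse_patterns <- function(mat) {
  pat <- apply(mat, 2, paste, collapse = "")
  upat <- unique(pat)
  idx <- match(pat, upat)
  states <- 1L + mat[, match(upat, pat), drop = FALSE]
  storage.mode(states) <- "integer"
  list(states = states, weights = as.numeric(tabulate(idx, length(upat))),
       col_pattern = idx)
}

# ---- exported operations ---------------------------------------------------

#' Fitch parsimony length of a tree on a binary character matrix
#'
#' Sums, over matrix columns, the minimum number of 0/1 state changes
#' required on the given topology (Fitch small parsimony).
#'
#' @param tree an `ape` phylo (rooted or unrooted; multifurcations beyond
#'   one basal trifurcation are not supported) or an `mp_tree`.
#' @param mat binary matrix with rownames matching the tree's tip labels
#'   (see [build_character_matrix()]).
#' @return numeric parsimony length.
#' @export
fitch_score <- function(tree, mat) {
  if (inherits(tree, "mp_tree")) tree <- tree$phy
  if (!setequal(tree$tip.label, rownames(mat))) {
    abort("tree tip labels must match matrix rownames",
          class = "mfclone_input_error")
  }
  if (ncol(mat) == 0) return(0)
  cp <- collapse_patterns(mat)
  ut <- phylo_to_utree(tree)
  fitch_ut(ut, cp$states, cp$weights)
}

phylo_to_utree <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  list(
    edge = phy$edge,
    tip_label = setNames(phy$tip.label, seq_len(ntip)),
    next_id = as.integer(ntip + phy$Nnode + 1L)
  )
}

# Stepwise-addition + NNI (or exhaustive) search over weighted patterns.
# Heuristic path runs `n_restarts` deterministic addition orders (the given
# order plus fixed-seed shuffles) and keeps the best-scoring result, ties
# broken by the lexicographically smallest canonical newick.
search_mp_core <- function(states, weights, labels, outgroup,
                           exhaustive_max = 9, n_restarts = 5) {
  n <- length(labels)
  if (n <= exhaustive_max) {
    best_score <- Inf
    best_nwk <- NULL
    best_ut <- NULL
    recurse <- function(ut, remaining) {
      if (length(remaining) == 0) {
        s <- fitch_ut(ut, states, weights)
        if (s < best_score) {
          best_score <<- s
          best_ut <<- ut
          best_nwk <<- ut_canonical_newick(ut, outgroup)
        } else if (s == best_score) {
          nwk <- ut_canonical_newick(ut, outgroup)
          if (nwk < best_nwk) {
            best_nwk <<- nwk
            best_ut <<- ut
          }
        }
        return(invisible())
      }
      for (k in seq_len(nrow(ut$edge))) {
        recurse(attach_tip(ut, k, remaining[1]), remaining[-1])
      }
    }
    recurse(utree3(labels[1:3]), labels[-(1:3)])
    return(list(ut = best_ut, score = best_score, newick = best_nwk,
                method = "exhaustive"))
  }
  run_once <- function(ord) {
    # deterministic stepwise addition in the given order
    ut <- utree3(ord[1:3])
    for (lab in ord[-(1:3)]) {
      best <- NULL
      best_s <- Inf
      for (k in seq_len(nrow(ut$edge))) {
        cand <- attach_tip(ut, k, lab)
        s <- fitch_ut(cand, states, weights)
        if (s < best_s) {
          best_s <- s
          best <- cand
        }
      }
      ut <- best
    }
    score <- fitch_ut(ut, states, weights)
    # NNI hill climbing, best improvement first, until a local optimum
    repeat {
      nbrs <- ut_nni_neighbors(ut)
      if (length(nbrs) == 0) break
      sc <- vapply(nbrs, fitch_ut, numeric(1), states = states,
                   weights = weights)
      if (min(sc) >= score) break
      ut <- nbrs[[which.min(sc)]]
      score <- min(sc)
    }
    list(ut = ut, score = score)
  }
  orders <- list(labels)
  if (n_restarts > 1) {
    for (r in seq_len(n_restarts - 1)) {
      orders[[r + 1]] <- with_seed(1000003L + r, sample(labels))
    }
  }
  best <- NULL
  best_nwk <- NULL
  for (ord in orders) {
    res <- run_once(ord)
    nwk <- ut_canonical_newick(res$ut, outgroup)
    if (is.null(best) || res$score < best$score ||
        (res$score == best$score && nwk < best_nwk)) {
      best <- res
      best_nwk <- nwk
    }
  }
  list(ut = best$ut, score = best$score, newick = best_nwk,
       method = "stepwise+NNI")
}

#' Maximum-parsimony tree search on a binary character matrix
#'
#' Finds a minimum-length topology under Fitch parsimony. For
#' `exhaustive_max` or fewer leaves every unrooted topology is enumerated,
#' guaranteeing the global optimum, with ties broken by the
#' lexicographically smallest canonical newick; above that, deterministic
#' stepwise addition (in matrix row order) followed by best-improvement NNI
#' hill climbing is used. The returned tree is displayed rooted at the
#' all-absent germline outgroup, the biologically known root.
#'
#' @param mat binary character matrix from [build_character_matrix()].
#' @param exhaustive_max largest leaf count for exhaustive search
#'   (default 9; enumeration grows as (2n-5)!! and is slow near the limit).
#' @param outgroup outgroup row name (defaults to the matrix's
#'   `"outgroup"` attribute).
#' @return An object of class `mp_tree`: fields `phy` (rooted `ape` phylo in
#'   canonical orientation), `score`, `outgroup`, `method`.
#' @export
search_mp_tree <- function(mat, exhaustive_max = 9, outgroup = NULL) {
  outgroup <- outgroup %||% attr(mat, "outgroup") %||% "normal"
  labels <- rownames(mat)
  if (length(labels) < 3) {
    abort("tree search needs at least 3 leaves (including the outgroup)",
          class = "mfclone_input_error")
  }
  if (!outgroup %in% labels) {
    abort("outgroup row not found in matrix", class = "mfclone_input_error")
  }
  cp <- collapse_patterns(mat)
  res <- search_mp_core(cp$states, cp$weights, labels, outgroup,
                        exhaustive_max)
  phy <- ape::read.tree(text = res$newick)
  structure(
    list(phy = phy, score = res$score, outgroup = outgroup,
         method = res$method),
    class = "mp_tree"
  )
}

#' @export
print.mp_tree <- function(x, ...) {
  cat("<mp_tree> ", length(x$phy$tip.label), " leaves, parsimony score ",
      x$score, " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Assign per-branch SNV counts by Fitch backtrace
#'
#' Each matrix column is assigned to the branch(es) where its
#' most-parsimonious state change occurs, via a deterministic Fitch
#' reconstruction on the rooted tree: the root prefers the ancestral
#' (absent) state, and ambiguous internal nodes inherit the parental state
#' when possible (changes are thus placed as close to the tips as the
#' parsimony sets allow). Homoplasy-free columns have a unique placement;
#' homoplastic columns contribute one count to each branch of their
#' reconstructed changes.
#'
#' Branch counts are written into `phy$edge.length`, so exported trees carry
#' SNV counts as branch lengths.
#'
#' @param mp an `mp_tree` from [search_mp_tree()].
#' @param mat the character matrix the tree was built from.
#' @return `mp` with added `edge_counts` (per-edge counts aligned to
#'   `phy$edge`) and updated `phy$edge.length`.
#' @export
assign_branch_counts <- function(mp, mat) {
  stopifnot(inherits(mp, "mp_tree"))
  phy <- ape::reorder.phylo(mp$phy, "postorder")
  if (!setequal(phy$tip.label, rownames(mat))) {
    abort("tree tip labels must match matrix rownames",
          class = "mfclone_input_error")
  }
  cp <- collapse_patterns(mat)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  P <- length(cp$weights)
  S <- matrix(0L, nnode, P)
  S[seq_len(ntip), ] <- cp$states[phy$tip.label, , drop = FALSE]
  edge <- phy$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    child <- S[ch, ]; acc <- S[p, ]
    if (acc[1] == 0L) {
      S[p, ] <- child
    } else {
      inter <- bitwAnd(acc, child)
      z <- inter == 0L
      inter[z] <- acc[z] + child[z]
      S[p, ] <- inter
    }
  }
  root <- ntip + 1L
  state <- matrix(0L, nnode, P)
  # root: prefer absent (germline) state where ambiguous
  state[root, ] <- ifelse(bitwAnd(S[root, ], 1L) > 0L, 1L, 2L)
  counts <- numeric(nrow(edge))
  for (k in rev(seq_len(nrow(edge)))) { # preorder
    p <- edge[k, 1]; ch <- edge[k, 2]
    ps <- state[p, ]
    keep <- bitwAnd(S[ch, ], ps) > 0L
    cs <- ifelse(keep, ps, S[ch, ]) # if parent state excluded, set is a singleton
    state[ch, ] <- cs
    counts[k] <- sum(cp$weights[cs != ps])
  }
  # map counts back to the original (canonical) edge ordering
  o <- match(paste(mp$phy$edge[, 1], mp$phy$edge[, 2]),
             paste(edge[, 1], edge[, 2]))
  mp$edge_counts <- counts[o]
  mp$phy$edge.length <- mp$edge_counts
  mp
}

#' Bootstrap support for internal branches
#'
#' Resamples matrix columns with replacement `n_reps` times, infers a
#' maximum-parsimony tree per replicate (stepwise addition + NNI), and
#' reports for each internal branch of the original tree the percentage of
#' replicate trees containing the same unrooted bipartition. Supports are
#' written into `phy$node.label` for export and plotting.
#'
#' @param mat binary character matrix (>= 4 leaves).
#' @param n_reps number of replicates (default 500).
#' @param seed RNG seed for reproducible resampling.
#' @param tree optional pre-computed `mp_tree`; inferred from `mat` if NULL.
#' @param exhaustive_max exhaustive-search cap passed to the original-tree
#'   search (replicate searches are always heuristic).
#' @return The `mp_tree` with `support` (tibble: `node`, `clade`,
#'   `support`) and `phy$node.label` set (empty where not applicable).
#' @export
bootstrap_support <- function(mat, n_reps = 500, seed = 1L, tree = NULL,
                              exhaustive_max = 9) {
  if (n_reps <= 0) {
    abort("`n_reps` must be positive", class = "mfclone_config_error")
  }
  if (nrow(mat) < 4) {
    abort("bootstrap needs >= 4 leaves", class = "mfclone_input_error")
  }
  mp <- tree %||% search_mp_tree(mat, exhaustive_max = exhaustive_max)
  outgroup <- mp$outgroup
  cp <- collapse_patterns(mat)
  labels <- rownames(mat)
  ncols <- ncol(mat)
  split_counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(ncols, ncols, replace = TRUE)
      w <- tabulate(cp$col_pattern[idx], nbins = length(cp$weights))
      use <- w > 0
      # random addition order per replicate: tie regions (no grouping
      # signal) then resolve differently across replicates instead of
      # inheriting the deterministic tie-break as spurious support
      res <- search_mp_core(cp$states[, use, drop = FALSE], w[use],
                            sample(labels), outgroup, exhaustive_max = 0,
                            n_restarts = 1)
      for (key in ut_splits(res$ut, outgroup)) {
        split_counts[[key]] <- (split_counts[[key]] %||% 0L) + 1L
      }
    }
  })
  # clade keys for internal nodes of the rooted original tree
  phy <- mp$phy
  ntip <- length(phy$tip.label)
  support <- tibble::tibble(node = integer(), clade = character(),
                            support = numeric())
  labs <- rep("", phy$Nnode)
  for (node in (ntip + 1L):(ntip + phy$Nnode)) {
    tips <- tips_below(phy, node)
    if (length(tips) < 2 || length(tips) > ntip - 2 || outgroup %in% tips) next
    key <- paste(sort(tips), collapse = "|")
    sup <- 100 * (split_counts[[key]] %||% 0L) / n_reps
    support <- dplyr::bind_rows(support, tibble::tibble(
      node = node, clade = key, support = sup
    ))
    labs[node - ntip] <- format(round(sup, 1))
  }
  mp$support <- support
  mp$n_reps <- n_reps
  mp$phy$node.label <- labs
  mp
}

tips_below <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, phy = phy))
}

#' Export an annotated tree as newick
#'
#' Branch lengths are per-branch SNV counts (when assigned) and internal
#' node labels bootstrap supports (when computed).
#'
#' @param mp an `mp_tree`.
#' @param path output file, or `NULL` to return the newick string.
#' @return the newick string, invisibly if written to a file.
#' @export
export_newick <- function(mp, path = NULL) {
  stopifnot(inherits(mp, "mp_tree"))
  s <- ape::write.tree(mp$phy)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname search_mp_tree
#' @param x an `mp_tree`.
#' @param ... unused.
#' @exportS3Method
tidy.mp_tree <- function(x, ...) {
  phy <- x$phy
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  out <- tibble::tibble(
    parent = phy$edge[, 1],
    node = child,
    label = ifelse(child <= ntip, phy$tip.label[child], NA_character_),
    is_internal = child > ntip,
    snv_count = if (!is.null(x$edge_counts)) x$edge_counts else NA_real_
  )
  if (!is.null(x$support)) {
    out <- dplyr::left_join(out, x$support[, c("node", "support")], by = "node")
  }
  out
}

#' @rdname search_mp_tree
#' @exportS3Method
glance.mp_tree <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$phy$tip.label),
    score = x$score,
    method = x$method,
    n_reps = x$n_reps %||% NA_integer_
  )
}
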