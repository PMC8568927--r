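#' Pairwise shared somatic SNVs between samples
#'
#' Computes exact set intersections of variant keys (`chrom:pos:ref:alt`)
#' between every pair of samples. Indel records (rows with
#' `variant_type == "indel"`) are excluded: the pairwise and phylogenetic
#' analyses are SNV-only.
#'
#' @param calls long tibble of filtered calls with a `sample` column.
#' @return An object of class `shared_matrix`: symmetric count matrix
#'   (diagonal = per-sample totals) plus per-sample key sets. Use
#'   [shared_variants()] for a pair's variant list and `tidy()` for a long
#'   tibble of pair counts.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   sample = c("A", "A", "B"), chrom = "chr1", pos = c(1, 2, 2),
#'   ref = "C", alt = "T"
#' )
#' tidy(pairwise_shared(calls))
pairwise_shared <- function(calls) {
  if (!"sample" %in% names(calls)) {
    abort("`calls` must have a `sample` column", class = "mfclone_input_error")
  }
  if ("variant_type" %in% names(calls)) {
    calls <- calls[calls$variant_type != "indel", , drop = FALSE]
  }
  samples <- sort(unique(calls$sample))
  if (length(samples) < 2) {
    abort("need >= 2 samples for pairwise analysis",
          class = "mfclone_input_error")
  }
  keys <- split(
    variant_key(calls$chrom, calls$pos, calls$ref, calls$alt),
    calls$sample
  )[samples]
  dup <- names(keys)[vapply(keys, anyDuplicated, integer(1)) > 0]
  if (length(dup) > 0) {
    abort(paste0("duplicate variant key within sample ", dup[1]),
          class = "mfclone_input_error")
  }
  n <- length(samples)
  counts <- matrix(0L, n, n, dimnames = list(samples, samples))
  diag(counts) <- vapply(keys, length, integer(1))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- length(intersect(keys[[i]], keys[[j]]))
        counts[i, j] <- counts[j, i] <- shared
      }
    }
  }
  structure(
    list(samples = samples, counts = counts, keys = keys),
    class = "shared_matrix"
  )
}

#' Shared variant keys for one sample pair
#'
#' @param x a `shared_matrix` from [pairwise_shared()].
#' @param a,b sample ids.
#' @return character vector of `chrom:pos:ref:alt` keys shared by `a` and `b`.
#' @export
shared_variants <- function(x, a, b) {
  stopifnot(inherits(x, "shared_matrix"))
  if (!all(c(a, b) %in% x$samples)) {
    abort("unknown sample id", class = "mfclone_input_error")
  }
  intersect(x$keys[[a]], x$keys[[b]])
}

#' @export
print.shared_matrix <- function(x, ...) {
  cat("<shared_matrix> ", length(x$samples), " samples\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname pairwise_shared
#' @param x a `shared_matrix`.
#' @param ... unused.
#' @exportS3Method
tidy.shared_matrix <- function(x, ...) {
  pairs <- which(upper.tri(x$counts), arr.ind = TRUE)
  tibble::tibble(
    sample_a = x$samples[pairs[, 1]],
    sample_b = x$samples[pairs[, 2]],
    shared = x$counts[pairs]
  )
}

#' Classify a small between-sample variant overlap
#'
#' Applies a fixed decision rule to the shared variants of a sample set,
#' using the overlap size and the median VAF of the shared variants in each
#' carrier:
#'
#' * `clonal_trunk`: count >= `min_trunk` and median VAF >= `clonal_floor`
#'   in every carrier — mutations acquired before metastatic seeding;
#' * `contamination_trace`: median VAF < `trace_ceiling` in exactly one
#'   sample while the others look clonal — compatible with sample-handling
#'   cross-contamination;
#' * `embryonic`: count <= `embryonic_max` with clonal VAFs in all
#'   carriers — early-developmental lineage-specific mutations;
#' * `unexplained` otherwise.
#'
#' Default thresholds (`min_trunk = 50`, `clonal_floor = 0.10`,
#' `trace_ceiling = 0.10`, `embryonic_max = 20`) separate the three observed
#' regimes (hundreds-strong clonal trunks; tens of low-VAF traces; <= ~10
#' clonal embryonic variants) with wide margins.
#'
#' @param shared_vafs long tibble with one row per (shared variant, carrier
#'   sample): columns `sample`, `vaf`, and a variant identifier column
#'   (`key`, or `chrom`+`pos`+`ref`+`alt`).
#' @param min_trunk,clonal_floor,trace_ceiling,embryonic_max rule thresholds.
#' @return An object of class `overlap_class` with fields `label`,
#'   `n_shared`, and `evidence` (per-sample median VAFs).
#' @export
classify_overlap <- function(shared_vafs, min_trunk = 50, clonal_floor = 0.10,
                             trace_ceiling = 0.10, embryonic_max = 20) {
  if (nrow(shared_vafs) == 0) {
    abort("shared variant list is empty", class = "mfclone_input_error")
  }
  if (!"key" %in% names(shared_vafs)) {
    shared_vafs$key <- variant_key(shared_vafs$chrom, shared_vafs$pos,
                                   shared_vafs$ref, shared_vafs$alt)
  }
  if (anyNA(shared_vafs$vaf)) {
    abort("missing VAF for a shared variant", class = "mfclone_input_error")
  }
  n_shared <- dplyr::n_distinct(shared_vafs$key)
  evidence <- shared_vafs |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n = dplyr::n(), median_vaf = median(.data$vaf), .groups = "drop"
    )
  med <- evidence$median_vaf
  label <- if (n_shared >= min_trunk && all(med >= clonal_floor)) {
    "clonal_trunk"
  } else if (sum(med < trace_ceiling) == 1 && nrow(evidence) >= 2) {
    "contamination_trace"
  } else if (n_shared <= embryonic_max && all(med >= clonal_floor)) {
    "embryonic"
  } else {
    "unexplained"
  }
  structure(
    list(label = label, n_shared = n_shared, evidence = evidence,
         thresholds = list(min_trunk = min_trunk, clonal_floor = clonal_floor,
                           trace_ceiling = trace_ceiling,
                           embryonic_max = embryonic_max)),
    class = "overlap_class"
  )
}

#' @export
print.overlap_class <- function(x, ...) {
  cat("<overlap_class> ", x$label, " (", x$n_shared, " shared variants)\n",
      sep = "")
  print(x$evidence)
  invisible(x)
}

#' Build a binary sample-by-variant character matrix
#'
#' Rows are samples plus an all-absent germline outgroup; columns are the
#' union of SNV keys across samples, ordered deterministically by
#' (chrom, pos, alt). Indels are excluded.
#'
#' @param calls long tibble of filtered calls with a `sample` column.
#' @param outgroup name of the appended all-zero outgroup row.
#' @return 0/1 integer matrix with an `"outgroup"` attribute; every column
#'   has at least one presence.
#' @export
build_character_matrix <- function(calls, outgroup = "normal") {
  if (!"sample" %in% names(calls) || dplyr::n_distinct(calls$sample) < 1) {
    abort("need at least one sample", class = "mfclone_input_error")
  }
  if ("variant_type" %in% names(calls)) {
    calls <- calls[calls$variant_type != "indel", , drop = FALSE]
  }
  samples <- sort(unique(calls$sample))
  if (outgroup %in% samples) {
    abort("outgroup name collides with a sample id",
          class = "mfclone_input_error")
  }
  u <- calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  cols <- variant_key(u$chrom, u$pos, u$ref, u$alt)
  mat <- matrix(0L, nrow = length(samples) + 1, ncol = length(cols),
                dimnames = list(c(samples, outgroup), cols))
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  mat[cbind(match(calls$sample, rownames(mat)), match(key, cols))] <- 1L
  attr(mat, "outgroup") <- outgroup
  mat
}
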