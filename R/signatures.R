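#' 96-channel trinucleotide substitution profile
#'
#' Counts single-base substitutions into the 96 pyrimidine-strand channels.
#' Purine-reference records are reverse-complemented before counting.
#' Non-autosomal records are excluded (sex chromosomes behave differently
#' under copy number and are conventionally left out of profiles), as are
#' indels and records with an unusable context (counted in the
#' `"n_skipped"` attribute, with a warning).
#'
#' @param mutations tibble with `ref`, `alt`, `context` columns (and
#'   optionally `chrom`, `variant_type`).
#' @return An object of class `profile96`: a named numeric vector of 96
#'   counts in canonical channel order.
#' @export
#' @examples
#' count_96(tibble::tibble(ref = "C", alt = "T", context = "ACA"))
count_96 <- function(mutations) {
  ch <- sbs96_channels()
  if ("variant_type" %in% names(mutations)) {
    mutations <- mutations[mutations$variant_type == "SNV", , drop = FALSE]
  }
  if ("chrom" %in% names(mutations)) {
    autosomes <- paste0("chr", 1:22)
    mutations <- mutations[
      mutations$chrom %in% c(autosomes, as.character(1:22)), , drop = FALSE
    ]
  }
  lab <- channel_of(mutations$ref, mutations$alt, mutations$context)
  n_skipped <- sum(is.na(lab))
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " record(s) skipped (bad context)"))
  }
  counts <- table(factor(lab[!is.na(lab)], levels = ch$channel))
  structure(setNames(as.numeric(counts), ch$channel),
            class = "profile96", n_skipped = n_skipped)
}

#' @export
print.profile96 <- function(x, ...) {
  cat("<profile96> ", sum(x), " substitutions\n", sep = "")
  invisible(x)
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

nnls_fit <- function(profile, sig_cols) {
  fit <- pracma::lsqnonneg(sig_cols, profile)
  list(coef = fit$x, sse = sum((profile - sig_cols %*% fit$x)^2))
}

#' Refit a 96-channel profile against a signature catalogue
#'
#' Greedy forward selection with non-negative least-squares sub-fits: the
#' profile is normalised to sum 1, and signatures are added one at a time,
#' each step picking the signature whose inclusion most reduces the
#' reconstruction sum of squares, stopping at `max_k` signatures or when the
#' improvement falls below `tol`. Weights below `min_weight` are then zeroed
#' and the remaining signatures refit (the standard refitting convention).
#' The procedure is deterministic.
#'
#' @param profile a [count_96()] profile (or 96-vector of counts).
#' @param signatures 96 x k signature probability matrix (see
#'   [read_signature_matrix()], [synthetic_signature_matrix()]).
#' @param max_k maximum number of active signatures (default 4).
#' @param min_weight smallest reportable loading (default 0.06).
#' @param tol minimum SSE improvement to keep adding signatures.
#' @return An object of class `signature_fit`: `loadings` (named, one per
#'   catalogue signature, inactive = 0), `residual` (SSE on the normalised
#'   profile), `n_active`.
#' @export
fit_signatures <- function(profile, signatures, max_k = 4, min_weight = 0.06,
                           tol = 1e-4) {
  p <- as.numeric(profile)
  if (length(p) != nrow(signatures)) {
    abort("profile and signature matrix must share the 96 channels",
          class = "mfclone_input_error")
  }
  if (sum(p) <= 0) {
    abort("profile is all zeros; loadings undefined",
          class = "mfclone_input_error")
  }
  p <- p / sum(p)
  sig_names <- colnames(signatures)
  active <- character(0)
  sse <- sum(p^2)
  repeat {
    if (length(active) >= max_k) break
    cand <- setdiff(sig_names, active)
    trial <- vapply(cand, function(s) {
      nnls_fit(p, signatures[, c(active, s), drop = FALSE])$sse
    }, numeric(1))
    if (min(trial) >= sse - tol) break
    active <- c(active, cand[which.min(trial)])
    sse <- min(trial)
  }
  fit <- nnls_fit(p, signatures[, active, drop = FALSE])
  w <- setNames(fit$coef, active)
  drop <- names(w)[w < min_weight]
  if (length(drop) > 0 && length(drop) < length(w)) {
    active <- setdiff(active, drop)
    fit <- nnls_fit(p, signatures[, active, drop = FALSE])
    w <- setNames(fit$coef, active)
  } else if (length(drop) == length(w) && length(w) > 0) {
    # keep the single best signature rather than reporting nothing
    best <- names(w)[which.max(w)]
    active <- best
    fit <- nnls_fit(p, signatures[, best, drop = FALSE])
    w <- setNames(fit$coef, best)
  }
  loadings <- setNames(rep(0, length(sig_names)), sig_names)
  loadings[names(w)] <- w
  structure(
    list(loadings = loadings, residual = fit$sse,
         n_active = sum(loadings > 0), profile = p),
    class = "signature_fit"
  )
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("<signature_fit> ", x$n_active, " active signature(s); residual SSE ",
      signif(x$residual, 3), "\n", sep = "")
  act <- sort(x$loadings[x$loadings > 0], decreasing = TRUE)
  for (s in names(act)) cat("  ", s, ": ", round(act[[s]], 3), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_signatures
#' @param x a `signature_fit`.
#' @param ... unused.
#' @exportS3Method
tidy.signature_fit <- function(x, ...) {
  tibble::tibble(
    signature = names(x$loadings),
    loading = unname(x$loadings),
    active = x$loadings > 0
  )
}

#' @rdname fit_signatures
#' @exportS3Method
glance.signature_fit <- function(x, ...) {
  tibble::tibble(n_active = x$n_active, residual = x$residual,
                 total_loading = sum(x$loadings))
}
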