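#' Read a signature definition matrix (COSMIC v3 tab format)
#'
#' Reads a tab-separated signature file whose first column (`Type`) holds
#' 96-channel labels such as `A[C>A]A` and whose remaining columns are one
#' probability vector per signature. Channel order in the file is arbitrary;
#' rows are normalised internally to the canonical channel order.
#'
#' @param path path to the TSV file.
#' @return A numeric matrix with 96 rows (canonical channel order, rownames
#'   set to channel labels) and one column per signature; each column sums
#'   to 1 within numerical tolerance.
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  type_col <- names(df)[1]
  channels <- sbs96_channels()$channel
  if (!setequal(df[[type_col]], channels)) {
    abort("signature file must contain exactly the 96 SBS channel labels")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[type_col]]
  mat <- mat[channels, , drop = FALSE]
  sums <- colSums(mat)
  if (any(mat < 0) || any(abs(sums - 1) > 1e-3)) {
    abort("signature columns must be probability vectors over the 96 channels")
  }
  sweep(mat, 2, sums, "/")
}

#' Write a signature matrix in COSMIC v3 tab format
#'
#' @param sigs 96-row signature matrix (columns = signatures).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- tibble::as_tibble(sigs)
  df <- dplyr::bind_cols(tibble::tibble(Type = rownames(sigs)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Synthetic single-base-substitution signature set
#'
#' A deterministic, fully synthetic stand-in for a reference SBS signature
#' catalogue, built from closed-form channel weights (no randomness). It is
#' not COSMIC data; each signature emulates the qualitative shape of the
#' COSMIC process it is named after, so that code written against the COSMIC
#' v3 file dialect can be exercised end-to-end:
#'
#' * `SBS1`: deamination-like, concentrated on `N[C>T]G` channels;
#' * `SBS5`: flat, clock-like, with mild T>C and C>T enrichment;
#' * `SBS40`: constructed as a heavily SBS5-correlated flat process
#'   (cosine similarity with SBS5 > 0.95), reproducing the practical
#'   confusability of the two clock-like signatures;
#' * `SBS18`: C>A-dominated (reactive-oxygen-like);
#' * `SBS2`: APOBEC-like, `T[C>T]N` and `T[C>G]N`.
#'
#' @return A 96 x 5 probability matrix (rows in canonical channel order).
#' @export
#' @examples
#' sigs <- synthetic_signature_matrix()
#' colSums(sigs)
synthetic_signature_matrix <- function() {
  ch <- sbs96_channels()
  n <- nrow(ch)
  norm1 <- function(w) w / sum(w)

  sbs1 <- rep(0.05 / (n - 4), n)
  sbs1[ch$sub == "C>T" & ch$three == "G"] <- 0.95 / 4

  ripple <- 1 + 0.3 * cos(2 * pi * seq_len(n) / 16)
  sbs5 <- ripple
  sbs5[ch$sub == "T>C"] <- sbs5[ch$sub == "T>C"] * 1.8
  sbs5[ch$sub == "C>T"] <- sbs5[ch$sub == "C>T"] * 1.4
  sbs5 <- norm1(sbs5)

  tilt <- rep(1, n)
  tilt[ch$sub == "C>A"] <- 1.6
  sbs40 <- norm1(0.82 * sbs5 + 0.18 * norm1(tilt))

  sbs18 <- rep(1, n)
  sbs18[ch$sub == "C>A"] <- 14
  sbs18[ch$sub == "C>A" & ch$five %in% c("G", "T")] <- 22
  sbs18 <- norm1(sbs18)

  sbs2 <- rep(0.04 / (n - 8), n)
  sbs2[ch$sub == "C>T" & ch$five == "T"] <- 0.70 / 4
  sbs2[ch$sub == "C>G" & ch$five == "T"] <- 0.26 / 4

  mat <- cbind(
    SBS1 = norm1(sbs1), SBS2 = norm1(sbs2), SBS5 = sbs5,
    SBS18 = sbs18, SBS40 = sbs40
  )
  rownames(mat) <- ch$channel
  mat
}
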