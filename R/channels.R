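#' Single-base-substitution channel conventions
#'
#' Somatic single-base substitutions are classified into 96 channels by the
#' pyrimidine-strand substitution (C>A, C>G, C>T, T>A, T>C, T>G) and the two
#' flanking bases. Substitutions reported with a purine reference are
#' reverse-complemented before classification, so e.g. a `T[G>A]C` event is
#' counted as `G[C>T]A`.
#'
#' @return A tibble with one row per channel in canonical order (substitution
#'   class, then 5' base, then 3' base, alphabetically), with columns
#'   `channel` (e.g. `"A[C>A]A"`), `sub`, `ref`, `alt`, `five`, `three`.
#' @export
#' @examples
#' sbs96_channels()
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(
    three = c("A", "C", "G", "T"),
    five = c("A", "C", "G", "T"),
    sub = subs,
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$sub, grid$five, grid$three), ]
  tibble::tibble(
    channel = paste0(grid$five, "[", grid$sub, "]", grid$three),
    sub = grid$sub,
    ref = substr(grid$sub, 1, 1),
    alt = substr(grid$sub, 3, 3),
    five = grid$five,
    three = grid$three
  )
}

#' Reverse-complement a DNA string (vectorised)
#'
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical 96-channel label for a substitution in context
#'
#' Maps (ref, alt, trinucleotide context) observed on either strand to the
#' pyrimidine-reference channel label. Records whose context is not a 3-mer
#' over A/C/G/T, or whose middle base disagrees with `ref`, yield `NA`.
#'
#' @param ref,alt single reference/alternate bases as sequenced.
#' @param context trinucleotide context centred on the variant, as sequenced.
#' @return character vector of channel labels (or `NA` for bad records).
#' @export
#' @examples
#' channel_of("G", "A", "TGC") # counted as G[C>T]A
channel_of <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  out <- rep(NA_character_, n)
  ok <- !is.na(context) & nchar(context) == 3 &
    !grepl("[^ACGT]", context) & substr(context, 2, 2) == ref &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  flip <- r %in% c("A", "G")
  if (any(flip)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    r[flip] <- comp[r[flip]]
    a[flip] <- comp[a[flip]]
    ctx[flip] <- revcomp(ctx[flip])
  }
  out[ok] <- paste0(
    substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3)
  )
  out
}
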