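#' Read gene models into the CDS-exon table used for fusion checks
#'
#' Accepts BED12 (blocks interpreted as CDS exons between `thickStart` and
#' `thickEnd`) or a minimal GFF3 subset (`CDS` features with `Parent=` or
#' `transcript_id` attributes). Requires the rtracklayer package.
#'
#' @param path BED12 or GFF3 file.
#' @return tibble with one row per CDS exon: `transcript`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading gene models requires the rtracklayer package")
  }
  if (grepl("\\.bed$", path)) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- purrr::map_dfr(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- if (!is.null(g$blocks)) g$blocks[[1]] else NULL
      thick <- g$thick
      if (is.null(blocks)) {
        ex <- tibble::tibble(start = GenomicRanges::start(g),
                             end = GenomicRanges::end(g))
      } else {
        abs_blocks <- GenomicRanges::shift(blocks, GenomicRanges::start(g) - 1L)
        ex <- tibble::tibble(start = GenomicRanges::start(abs_blocks),
                             end = GenomicRanges::end(abs_blocks))
      }
      ts <- GenomicRanges::start(thick)
      te <- GenomicRanges::end(thick)
      ex$start <- pmax(ex$start, ts)
      ex$end <- pmin(ex$end, te)
      ex <- ex[ex$end >= ex$start, , drop = FALSE]
      tibble::tibble(
        transcript = as.character(g$name), chrom = as.character(GenomicRanges::seqnames(g)),
        strand = as.character(GenomicRanges::strand(g)),
        start = ex$start, end = ex$end
      )
    })
    return(out)
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  cds <- gr[gr$type == "CDS"]
  parent <- if (!is.null(cds$Parent)) {
    vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  } else as.character(cds$transcript_id)
  tibble::tibble(
    transcript = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
}

# CDS bases of `tx_exons` upstream of `pos` in transcript orientation.
# `inclusive` counts the breakpoint base itself.
cds_upstream_length <- function(tx_exons, pos, inclusive) {
  total <- 0L
  for (i in seq_len(nrow(tx_exons))) {
    s <- tx_exons$start[i]; e <- tx_exons$end[i]
    if (tx_exons$strand[i] == "+") {
      hi <- if (inclusive) pos else pos - 1L
      total <- total + max(0L, min(e, hi) - s + 1L)
    } else {
      lo <- if (inclusive) pos else pos + 1L
      total <- total + max(0L, e - max(s, lo) + 1L)
    }
  }
  total
}

#' Reading-frame check for a putative fusion
#'
#' Determines whether a structural-variant junction joining two genes
#' produces an in-frame fusion transcript. Each breakpoint is annotated to
#' a transcript's CDS; the fusion is `in_frame` when (a) the junction joins
#' the partners on one transcriptional strand (both partners joined in
#' their coding sense, or both inverted together) and (b) the cumulative
#' CDS lengths upstream of the two breakpoints are congruent modulo 3, so
#' the downstream partner continues in codon phase. A breakpoint outside
#' any CDS yields `non_coding`.
#'
#' @param breakpoints two-row tibble (5' partner first): `chrom`, `pos`
#'   (1-based; the last base retained from the 5' partner and the first
#'   base retained of the 3' partner), `strand` (orientation of the joined
#'   segment, `"+"`/`"-"`).
#' @param gene_models CDS-exon tibble (see [read_gene_models()]).
#' @return one-row tibble: `label` (`in_frame`/`out_of_frame`/`non_coding`),
#'   `transcript_5`, `transcript_3`, `cds_upstream_5`, `cds_upstream_3`.
#' @export
fusion_frame_check <- function(breakpoints, gene_models) {
  stopifnot(nrow(breakpoints) == 2)
  locate <- function(chrom, pos) {
    hit <- gene_models[
      gene_models$chrom == chrom & gene_models$start <= pos &
        gene_models$end >= pos, , drop = FALSE
    ]
    if (nrow(hit) == 0) return(NULL)
    gene_models[gene_models$transcript == hit$transcript[1], , drop = FALSE]
  }
  tx5 <- locate(breakpoints$chrom[1], breakpoints$pos[1])
  tx3 <- locate(breakpoints$chrom[2], breakpoints$pos[2])
  res <- function(label, t5 = NA, t3 = NA, l5 = NA, l3 = NA) {
    tibble::tibble(label = label, transcript_5 = t5, transcript_3 = t3,
                   cds_upstream_5 = l5, cds_upstream_3 = l3)
  }
  if (is.null(tx5) || is.null(tx3)) return(res("non_coding"))
  sense5 <- tx5$strand[1] == breakpoints$strand[1]
  sense3 <- tx3$strand[1] == breakpoints$strand[2]
  if (sense5 != sense3) {
    return(res("out_of_frame", tx5$transcript[1], tx3$transcript[1]))
  }
  l5 <- cds_upstream_length(tx5, breakpoints$pos[1], inclusive = TRUE)
  l3 <- cds_upstream_length(tx3, breakpoints$pos[2], inclusive = FALSE)
  label <- if ((l5 - l3) %% 3 == 0) "in_frame" else "out_of_frame"
  res(label, tx5$transcript[1], tx3$transcript[1], l5, l3)
}
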