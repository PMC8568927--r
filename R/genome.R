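# hg19 (GRCh37) autosome lengths in bp.
HG19_AUTOSOME_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566
)

#' Genome model for cohort simulation
#'
#' Defines chromosome names and lengths used when placing simulated
#' mutations, heterozygous SNPs and read-count windows. The default is a
#' miniature genome: the 22 autosomes scaled to 1/100 of their hg19 lengths,
#' which keeps desk-scale simulations fast while preserving the per-chromosome
#' structure that the copy-number and phasing stages depend on. Real hg19
#' lengths are available with `scale = 1`.
#'
#' Trinucleotide context frequencies are uniform by default; a named
#' 32-element frequency vector over pyrimidine-centred trinucleotides may be
#' supplied for genome-derived weighting.
#'
#' @param scale multiplier applied to hg19 autosome lengths (default 0.01).
#' @param chroms chromosome names to include (subset of chr1..chr22).
#' @param trinuc_freq `"uniform"` or a named non-negative vector over
#'   pyrimidine-centred trinucleotides (e.g. `"ACA"`).
#' @return A list of class `genome_model` with elements `chromosomes`
#'   (tibble: `chrom`, `length`) and `trinuc_freq`.
#' @export
#' @examples
#' genome_model()
#' genome_model(chroms = c("chr17", "chr18"))
genome_model <- function(scale = 0.01, chroms = names(HG19_AUTOSOME_LENGTHS),
                         trinuc_freq = "uniform") {
  if (!all(chroms %in% names(HG19_AUTOSOME_LENGTHS))) {
    abort("unknown chromosome name; autosomes chr1..chr22 are supported")
  }
  if (scale <= 0) abort("`scale` must be positive")
  lens <- pmax(1L, as.integer(round(HG19_AUTOSOME_LENGTHS[chroms] * scale)))
  if (identical(trinuc_freq, "uniform")) {
    ctx <- pyrimidine_trinucs()
    trinuc_freq <- setNames(rep(1 / length(ctx), length(ctx)), ctx)
  } else {
    if (is.null(names(trinuc_freq)) || any(trinuc_freq < 0)) {
      abort("`trinuc_freq` must be a named non-negative vector")
    }
    trinuc_freq <- trinuc_freq / sum(trinuc_freq)
  }
  structure(
    list(
      chromosomes = tibble::tibble(chrom = chroms, length = unname(lens)),
      trinuc_freq = trinuc_freq
    ),
    class = "genome_model"
  )
}

# 32 pyrimidine-centred trinucleotides (middle base C or T).
pyrimidine_trinucs <- function() {
  g <- expand.grid(
    three = c("A", "C", "G", "T"),
    mid = c("C", "T"),
    five = c("A", "C", "G", "T"),
    stringsAsFactors = FALSE
  )
  sort(paste0(g$five, g$mid, g$three))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(
    "<genome_model> ", nrow(x$chromosomes), " chromosomes, total ",
    format(sum(x$chromosomes$length), big.mark = ","), " bp\n",
    sep = ""
  )
  invisible(x)
}
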