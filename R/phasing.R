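#' Phase a whole-chromosome event to a homolog via germline het SNPs
#'
#' Orients each heterozygous SNP by which allele is elevated in a reference
#' sample (typically the metastatic primary tumor) and measures in a test
#' sample the fraction of informative SNPs whose same allele is elevated.
#' A concordance fraction at or above `concordance_threshold` means both
#' samples lost/gained the same homolog (`same_as_reference`); at or below
#' `1 - concordance_threshold`, different homologs
#' (`different_from_reference`). When the test sample's VAFs remain centred
#' on 0.5 despite the copy change (`|median - 0.5| < delta`) the event is
#' `biallelic`; anything else is `indeterminate`. Both samples are assumed
#' to carry a whole-chromosome event on this chromosome.
#'
#' @param het_snps one chromosome's het-SNP table (wide, as produced by
#'   [simulate_cohort()]): `chrom`, `pos`, `vaf_normal`, `vaf_<sample>`
#'   columns.
#' @param reference_sample,test_sample sample ids.
#' @param delta allele-imbalance margin around 0.5 (default 0.05).
#' @param concordance_threshold fraction required for a same/different
#'   call (default 0.9).
#' @param min_snps minimum informative SNPs (default 20).
#' @param het_range accepted normal VAF window for heterozygosity
#'   (default `c(0.25, 0.75)`).
#' @return An object of class `phase_call`: `homolog_call`,
#'   `concordance_fraction`, `n_informative`, `reason`, and `snps`
#'   (per-SNP reference/test VAF scatter data).
#' @export
phase_event <- function(het_snps, reference_sample, test_sample,
                        delta = 0.05, concordance_threshold = 0.9,
                        min_snps = 20, het_range = c(0.25, 0.75)) {
  vr_col <- paste0("vaf_", reference_sample)
  vt_col <- paste0("vaf_", test_sample)
  if (!all(c("vaf_normal", vr_col, vt_col) %in% names(het_snps))) {
    abort("het-SNP table lacks required VAF columns",
          class = "mfclone_input_error")
  }
  het <- het_snps[
    het_snps$vaf_normal >= het_range[1] & het_snps$vaf_normal <= het_range[2],
    , drop = FALSE
  ]
  vr <- het[[vr_col]]
  vt <- het[[vt_col]]
  informative <- abs(vr - 0.5) > delta
  n_inf <- sum(informative)
  snps <- tibble::tibble(
    chrom = het$chrom, pos = het$pos, vaf_reference = vr, vaf_test = vt,
    informative = informative
  )
  mk <- function(call, conc, reason = NA_character_) {
    structure(
      list(homolog_call = call, concordance_fraction = conc,
           n_informative = n_inf, reference_sample = reference_sample,
           test_sample = test_sample, reason = reason, snps = snps),
      class = "phase_call"
    )
  }
  if (n_inf < min_snps) {
    return(mk("indeterminate", NA_real_,
              paste0("only ", n_inf, " informative SNPs (need ", min_snps, ")")))
  }
  same_dir <- sign(vt[informative] - 0.5) == sign(vr[informative] - 0.5) &
    vt[informative] != 0.5
  conc <- mean(same_dir)
  if (conc >= concordance_threshold) return(mk("same_as_reference", conc))
  if (conc <= 1 - concordance_threshold) {
    return(mk("different_from_reference", conc))
  }
  if (abs(median(vt[informative]) - 0.5) < delta) {
    return(mk("biallelic", conc))
  }
  mk("indeterminate", conc, "intermediate concordance with allele imbalance")
}

#' @export
print.phase_call <- function(x, ...) {
  cat("<phase_call> ", x$reference_sample, " vs ", x$test_sample, ": ",
      x$homolog_call,
      if (!is.na(x$concordance_fraction)) {
        paste0(" (concordance ", round(x$concordance_fraction, 3), ", ",
               x$n_informative, " SNPs)")
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname phase_event
#' @param x a `phase_call`.
#' @param ... unused.
#' @exportS3Method
tidy.phase_call <- function(x, ...) x$snps

#' @rdname phase_event
#' @exportS3Method
glance.phase_call <- function(x, ...) {
  tibble::tibble(
    reference_sample = x$reference_sample, test_sample = x$test_sample,
    homolog_call = x$homolog_call,
    concordance_fraction = x$concordance_fraction,
    n_informative = x$n_informative
  )
}

#' Exact one-sided binomial concordance test
#'
#' Tail probability P(X >= n_concordant | n_total, p0) for the null that
#' homolog concordance between related tumor pairs is a fair coin: the test
#' behind "related tumors always lost the same chromosome homolog".
#'
#' @param n_concordant number of concordant pairs.
#' @param n_total number of informative (monoallelic, related) pairs.
#' @param p0 null concordance probability (default 0.5).
#' @return list of class `concordance_test`: `p_value`, `n_concordant`,
#'   `n_total`, `p0`.
#' @export
#' @examples
#' concordance_binomial_test(13, 13)$p_value # 0.5^13 ~ 1.2e-4
concordance_binomial_test <- function(n_concordant, n_total, p0 = 0.5) {
  if (n_total < 1) {
    abort("`n_total` must be >= 1", class = "mfclone_input_error")
  }
  if (n_concordant < 0 || n_concordant > n_total) {
    abort("`n_concordant` must lie in [0, n_total]",
          class = "mfclone_input_error")
  }
  p <- binom.test(n_concordant, n_total, p = p0,
                  alternative = "greater")$p.value
  structure(
    list(p_value = p, n_concordant = n_concordant, n_total = n_total, p0 = p0),
    class = "concordance_test"
  )
}

#' @export
print.concordance_test <- function(x, ...) {
  cat("<concordance_test> ", x$n_concordant, "/", x$n_total,
      " concordant; one-sided P = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname concordance_binomial_test
#' @param x a `concordance_test`.
#' @param ... unused.
#' @export
glance.concordance_test <- function(x, ...) {
  tibble::tibble(n_concordant = x$n_concordant, n_total = x$n_total,
                 p0 = x$p0, p_value = x$p_value)
}

#' VAF-based tumor purity estimate
#'
#' For clonal heterozygous variants on copy-neutral (diploid) regions the
#' expected VAF is purity/2, so purity is estimated as twice the median
#' VAF, clipped to (0, 1]. Samples below 30% purity are flagged, the usual
#' inclusion threshold for this analysis.
#'
#' @param vafs numeric VAFs of clonal candidate variants on copy-neutral
#'   regions.
#' @param min_sites minimum number of sites (default 20).
#' @param flag_below inclusion flag threshold (default 0.30).
#' @return one-row tibble: `purity`, `n_sites`, `flagged`.
#' @export
estimate_purity <- function(vafs, min_sites = 20, flag_below = 0.30) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_sites) {
    abort(paste0("need >= ", min_sites, " VAFs to estimate purity"),
          class = "mfclone_input_error")
  }
  purity <- min(2 * median(vafs), 1)
  tibble::tibble(
    purity = purity, n_sites = length(vafs),
    flagged = purity < flag_below
  )
}
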