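#' Read a somatic call table (TSV dialect or VCF 4.2)
#'
#' The TSV dialect has columns `chrom, pos (1-based), ref, alt, vaf, depth,
#' alt_fwd, alt_rev, in_normal` plus any extras (`normal_depth`,
#' `caller_set`, `population_flag`, `variant_type`, `context`). VCF input
#' (via the vcfR package) expects `AD`/`DP` FORMAT fields and `SAF`/`SAR`
#' INFO strand counts as written by [write_calls_vcf()].
#'
#' @param path input file; format chosen by extension (`.vcf` vs anything else).
#' @return tibble of calls, one row per variant observation.
#' @export
read_calls <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    return(read_calls_vcf(path))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "vaf", "depth", "alt_fwd",
            "alt_rev", "in_normal")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("call table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "mfclone_input_error")
  }
  tibble::as_tibble(df)
}

read_calls_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  dp <- as.integer(vcfR::extract.gt(v, element = "DP")[, 1])
  alt_reads <- as.integer(vapply(strsplit(ad, ","), `[`, character(1), 2))
  info <- vcfR::getINFO(v)
  get_info <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.integer(m)
  }
  saf <- get_info("SAF"); sar <- get_info("SAR")
  tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    vaf = alt_reads / pmax(dp, 1), depth = dp,
    alt_fwd = saf, alt_rev = sar,
    in_normal = grepl("(?:^|;)IN_NORMAL(?:;|$)", info)
  )
}

#' Write one sample's somatic calls as VCF 4.2
#'
#' Emits `AD` (ref,alt) and `DP` FORMAT fields plus `SAF`/`SAR` INFO strand
#' counts, and an `IN_NORMAL` INFO flag when the variant was seen in the
#' matched normal.
#'
#' @param calls tibble of calls for one sample.
#' @param path output path.
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_name = "TUMOR") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mfclone",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads reverse strand\">",
    "##INFO=<ID=IN_NORMAL,Number=0,Type=Flag,Description=\"Variant observed in matched normal\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  alt_reads <- calls$alt_fwd + calls$alt_rev
  info <- paste0("SAF=", calls$alt_fwd, ";SAR=", calls$alt_rev,
                 ifelse(calls$in_normal, ";IN_NORMAL", ""))
  body <- paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", info,
    "AD:DP", paste0(calls$depth - alt_reads, ",", alt_reads, ":", calls$depth),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population-variant blacklist
#'
#' Accepts either a dbSNP-style VCF (positions + alleles) or a 4-column TSV
#' (`chrom, pos, ref, alt`).
#'
#' @param path blacklist file.
#' @return character vector of variant keys `chrom:pos:ref:alt`.
#' @export
read_blacklist <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    return(paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"))
  }
  df <- readr::read_tsv(
    path, col_names = c("chrom", "pos", "ref", "alt"),
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample call tables (TSV dialect and VCF 4.2), the het-SNP and
#' window-count tables, and the ground truth as a JSON sidecar.
#'
#' @param cohort an `mf_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in setdiff(cohort$samples$sample, "normal")) {
    sc <- dplyr::filter(cohort$calls, .data$sample == s) |>
      dplyr::select(-"sample")
    readr::write_tsv(sc, file.path(dir, paste0("calls_", s, ".tsv")),
                     progress = FALSE)
    write_calls_vcf(sc, file.path(dir, paste0("calls_", s, ".vcf")),
                    sample_name = s)
  }
  readr::write_tsv(cohort$het_snps, file.path(dir, "het_snps.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$windows, file.path(dir, "windows.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      variants = truth$variants, vafs = truth$vafs, cna = truth$cna,
      snp_phase = truth$snp_phase, tree = truth$tree
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, toupper(ref), toupper(alt), sep = ":")
}
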