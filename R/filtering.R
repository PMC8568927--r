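#' Strict somatic-filter configuration
#'
#' Defaults encode the strict tumor-normal contract used for phylogenetic
#' analyses: at least 20 reads of normal coverage, absence from the matched
#' normal, alt support on both strands with a two-read floor, a minimum VAF
#' of 0.01, the intersection of the two callers, and removal of population
#' variants via a position+allele blacklist. Two blacklist stringency tiers
#' are conventional: an aggressive tier for tree building and a lenient tier
#' for signature/driver analyses (extensive SNP filtering can skew signature
#' results) — pass the appropriate key set as `blacklist`.
#'
#' @param min_normal_depth minimum reads in the matched normal.
#' @param min_alt_reads minimum supporting reads.
#' @param min_vaf minimum variant allele frequency.
#' @param require_both_strands require alt reads on both strands.
#' @param require_caller_intersection require both callers to report the call.
#' @param require_absent_in_normal reject calls flagged present in the normal.
#' @param blacklist character vector of `chrom:pos:ref:alt` keys (see
#'   [read_blacklist()]), or `NULL`.
#' @param indel_proximity_bp reject SNVs within this many bp of an indel
#'   call in the same sample (0 disables).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_normal_depth = 20, min_alt_reads = 2,
                          min_vaf = 0.01, require_both_strands = TRUE,
                          require_caller_intersection = TRUE,
                          require_absent_in_normal = TRUE,
                          blacklist = NULL, indel_proximity_bp = 3) {
  if (min_normal_depth < 0 || min_alt_reads < 0 || min_vaf < 0 ||
      indel_proximity_bp < 0) {
    abort("filter thresholds must be >= 0", class = "mfclone_config_error")
  }
  structure(
    list(
      min_normal_depth = min_normal_depth, min_alt_reads = min_alt_reads,
      min_vaf = min_vaf, require_both_strands = require_both_strands,
      require_caller_intersection = require_caller_intersection,
      require_absent_in_normal = require_absent_in_normal,
      blacklist = blacklist, indel_proximity_bp = indel_proximity_bp
    ),
    class = "filter_config"
  )
}

#' Apply the strict somatic-call filters
#'
#' Retains calls satisfying every enabled rule, in input order. Each
#' rejected call is annotated with the first failing rule; the rejection log
#' is attached as the `"rejections"` attribute and retrievable with
#' [filter_rejections()].
#'
#' Rule order: normal coverage, absent-in-normal, both strands, minimum alt
#' reads, minimum VAF, caller intersection, blacklist, indel proximity.
#' Records without a `caller_set` column are treated as intersection-passing
#' (with a warning), since third-party tables may not carry caller
#' provenance.
#'
#' @param calls tibble of somatic calls (may include a `sample` column for
#'   multi-sample tables; the indel-proximity rule is applied per sample).
#' @param config a [filter_config()].
#' @return The retained calls, with a `"rejections"` attribute
#'   (tibble: `key`, `sample`, `rule`).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   chrom = "chr1", pos = c(100, 200), ref = "C", alt = "T",
#'   vaf = c(0.3, 0.3), depth = 40, alt_fwd = c(6, 12), alt_rev = c(6, 0),
#'   normal_depth = 30, in_normal = FALSE
#' )
#' apply_strict_filters(calls, filter_config())
apply_strict_filters <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(calls) == 0) {
    out <- calls
    attr(out, "rejections") <- tibble::tibble(
      key = character(), sample = character(), rule = character()
    )
    return(out)
  }
  bad <- which(calls$vaf < 0 | calls$vaf > 1 | calls$pos < 1 |
                 (calls$alt_fwd + calls$alt_rev) > calls$depth)
  if (length(bad) > 0) {
    abort(
      paste0("malformed call record at row ", bad[1], " (",
             variant_key(calls$chrom[bad[1]], calls$pos[bad[1]],
                         calls$ref[bad[1]], calls$alt[bad[1]]), ")"),
      class = "mfclone_input_error"
    )
  }

  n <- nrow(calls)
  rule <- rep(NA_character_, n)
  fail <- function(cond, name) {
    rule <<- ifelse(is.na(rule) & cond, name, rule)
  }

  if ("normal_depth" %in% names(calls)) {
    fail(calls$normal_depth < config$min_normal_depth, "normal_coverage")
  }
  in_normal <- if ("in_normal" %in% names(calls)) calls$in_normal else
    calls$present_in_normal
  if (config$require_absent_in_normal && !is.null(in_normal)) {
    fail(in_normal, "in_normal")
  }
  alt_reads <- calls$alt_fwd + calls$alt_rev
  if (config$require_both_strands) {
    fail(calls$alt_fwd < 1 | calls$alt_rev < 1, "strand")
  }
  fail(alt_reads < config$min_alt_reads, "min_alt_reads")
  fail(calls$vaf < config$min_vaf, "min_vaf")
  if (config$require_caller_intersection) {
    if ("caller_set" %in% names(calls)) {
      both <- grepl("mutect2", calls$caller_set) & grepl("varscan", calls$caller_set)
      fail(!both, "caller_intersection")
    } else {
      warn("no `caller_set` column; treating all calls as intersection-passing")
    }
  }
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  if (!is.null(config$blacklist)) {
    fail(key %in% config$blacklist, "blacklist")
  }
  if (config$indel_proximity_bp > 0 && "variant_type" %in% names(calls)) {
    sample_col <- if ("sample" %in% names(calls)) calls$sample else rep("", n)
    is_indel <- calls$variant_type == "indel"
    near <- rep(FALSE, n)
    for (s in unique(sample_col[is_indel])) {
      idx_i <- which(is_indel & sample_col == s)
      idx_s <- which(!is_indel & sample_col == s)
      if (length(idx_i) == 0 || length(idx_s) == 0) next
      for (ci in unique(calls$chrom[idx_i])) {
        ip <- calls$pos[idx_i][calls$chrom[idx_i] == ci]
        sp_idx <- idx_s[calls$chrom[idx_s] == ci]
        if (length(sp_idx) == 0) next
        d <- vapply(calls$pos[sp_idx], function(p) min(abs(p - ip)), numeric(1))
        near[sp_idx[d <= config$indel_proximity_bp]] <- TRUE
      }
    }
    fail(near, "indel_proximity")
  }

  keep <- is.na(rule)
  out <- calls[keep, , drop = FALSE]
  attr(out, "rejections") <- tibble::tibble(
    key = key[!keep],
    sample = if ("sample" %in% names(calls)) calls$sample[!keep] else
      rep(NA_character_, sum(!keep)),
    rule = rule[!keep]
  )
  out
}

#' Rejection log from a strict-filter run
#'
#' @param x result of [apply_strict_filters()].
#' @return tibble with `key`, `sample`, `rule` for each rejected call.
#' @export
filter_rejections <- function(x) {
  attr(x, "rejections") %||% tibble::tibble(
    key = character(), sample = character(), rule = character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a pair whitelist from strict calls of two samples
#'
#' @param strict_a,strict_b strictly filtered call tables of the two samples.
#' @return character vector of unique variant keys.
#' @export
pair_whitelist <- function(strict_a, strict_b) {
  unique(c(
    variant_key(strict_a$chrom, strict_a$pos, strict_a$ref, strict_a$alt),
    variant_key(strict_b$chrom, strict_b$pos, strict_b$ref, strict_b$alt)
  ))
}

#' Whitelist relaxed recall of shared variants
#'
#' Re-queries each sample's unfiltered (relaxed) call set at whitelisted
#' positions: a whitelist variant is recalled in a sample when the relaxed
#' set reports it with at least `min_alt_reads` supporting reads, regardless
#' of strict-filter status. This recovers shared subclonal variants (e.g.
#' contamination traces) that strict filtering discards. Strict calls of a
#' sample are by construction a subset of its recalled set whenever the
#' whitelist covers them.
#'
#' @param whitelist character vector of `chrom:pos:ref:alt` keys, or a
#'   tibble with those four columns (see [pair_whitelist()]).
#' @param relaxed_calls long tibble of unfiltered calls with a `sample`
#'   column.
#' @param min_alt_reads recall support floor (default 2).
#' @return tibble of recalled calls (subset of `relaxed_calls` rows).
#' @export
whitelist_recall <- function(whitelist, relaxed_calls, min_alt_reads = 2) {
  if (is.data.frame(whitelist)) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(whitelist))) {
      abort("whitelist table must have chrom/pos/ref/alt columns",
            class = "mfclone_input_error")
    }
    whitelist <- variant_key(whitelist$chrom, whitelist$pos,
                             whitelist$ref, whitelist$alt)
  }
  if (length(whitelist) > 0 &&
      !all(grepl("^[^:]+:[0-9]+:[A-Za-z]+:[A-Za-z]+$", whitelist))) {
    abort("whitelist keys must be chrom:pos:ref:alt",
          class = "mfclone_input_error")
  }
  if (length(whitelist) == 0 || nrow(relaxed_calls) == 0) {
    return(relaxed_calls[0, , drop = FALSE])
  }
  key <- variant_key(relaxed_calls$chrom, relaxed_calls$pos,
                     relaxed_calls$ref, relaxed_calls$alt)
  support <- relaxed_calls$alt_fwd + relaxed_calls$alt_rev
  relaxed_calls[key %in% whitelist & support >= min_alt_reads, , drop = FALSE]
}
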