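#' Analysis settings for the per-patient pipeline
#'
#' Surfaces every stage's tunable thresholds with their defaults.
#'
#' @param filters a [filter_config()].
#' @param min_trunk,clonal_floor,trace_ceiling,embryonic_max overlap
#'   classification thresholds (see [classify_overlap()]).
#' @param bootstrap_reps bootstrap replicates for tree support.
#' @param exhaustive_max exhaustive-search cap for tree inference.
#' @param whole_chrom_fraction whole-chromosome event threshold.
#' @param phase_delta,phase_concordance,phase_min_snps phasing parameters
#'   (see [phase_event()]).
#' @param min_purity purity inclusion flag threshold.
#' @param seed seed for the bootstrap resampling.
#' @return list of class `patient_config`.
#' @export
patient_config <- function(filters = filter_config(), min_trunk = 50,
                           clonal_floor = 0.10, trace_ceiling = 0.10,
                           embryonic_max = 20, bootstrap_reps = 500,
                           exhaustive_max = 9, whole_chrom_fraction = 0.9,
                           phase_delta = 0.05, phase_concordance = 0.9,
                           phase_min_snps = 20, min_purity = 0.30,
                           seed = 1L) {
  structure(
    list(filters = filters, min_trunk = min_trunk,
         clonal_floor = clonal_floor, trace_ceiling = trace_ceiling,
         embryonic_max = embryonic_max, bootstrap_reps = bootstrap_reps,
         exhaustive_max = exhaustive_max,
         whole_chrom_fraction = whole_chrom_fraction,
         phase_delta = phase_delta, phase_concordance = phase_concordance,
         phase_min_snps = phase_min_snps, min_purity = min_purity,
         seed = as.integer(seed)),
    class = "patient_config"
  )
}

#' Bundle one patient's inputs for the pipeline
#'
#' @param patient_id patient identifier.
#' @param cohort an `mf_cohort` (in-memory data), or `NULL` when `dir` is
#'   given.
#' @param dir directory previously written by [write_cohort()].
#' @param config a [patient_config()].
#' @param signatures signature matrix for refitting.
#' @return list of class `patient_bundle`.
#' @export
patient_bundle <- function(patient_id, cohort = NULL, dir = NULL,
                           config = patient_config(),
                           signatures = synthetic_signature_matrix()) {
  if (is.null(cohort)) {
    if (is.null(dir)) abort("give either `cohort` or `dir`")
    samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                               show_col_types = FALSE, progress = FALSE)
    calls <- purrr::map_dfr(
      setdiff(samples$sample, "normal"),
      function(s) {
        dplyr::mutate(
          read_calls(file.path(dir, paste0("calls_", s, ".tsv"))),
          sample = s, .before = 1
        )
      }
    )
    cohort <- structure(
      list(
        samples = samples, calls = calls,
        het_snps = readr::read_tsv(file.path(dir, "het_snps.tsv"),
                                   show_col_types = FALSE, progress = FALSE),
        windows = readr::read_tsv(file.path(dir, "windows.tsv"),
                                  show_col_types = FALSE, progress = FALSE),
        truth = NULL, config = NULL
      ),
      class = "mf_cohort"
    )
  }
  n_normal <- sum(cohort$samples$role == "blood_normal")
  if (n_normal != 1) {
    abort("bundle must contain exactly one blood_normal sample",
          class = "mfclone_input_error")
  }
  structure(
    list(patient_id = patient_id, cohort = cohort, config = config,
         signatures = signatures),
    class = "patient_bundle"
  )
}

#' Run the full per-patient analysis
#'
#' Orchestrates strict filtering, purity estimation, pairwise shared-SNV
#' analysis with overlap classification, maximum-parsimony phylogeny with
#' branch counts and bootstrap supports, per-sample signature refitting,
#' copy-number segmentation with whole-chromosome calls, chromothripsis
#' detection, homolog phasing between the inferred metastatic primary and
#' every related sample, and the homolog-concordance binomial test.
#' Deterministic under a fixed `config$seed`. With fewer than two tumor
#' samples the clonality stage is skipped with a logged reason; signatures
#' and copy number are still produced.
#'
#' @param bundle a [patient_bundle()].
#' @param outdir optional directory for report artifacts (TSV tables +
#'   newick tree). With `force = FALSE` an existing completed report
#'   directory is left untouched and reloaded lazily.
#' @param force recompute even when `outdir` holds a completed report.
#' @return list of class `patient_report`.
#' @export
run_patient <- function(bundle, outdir = NULL, force = FALSE) {
  stopifnot(inherits(bundle, "patient_bundle"))
  if (!is.null(outdir) && !force &&
      file.exists(file.path(outdir, "report_complete"))) {
    return(invisible(structure(
      list(patient_id = bundle$patient_id, outdir = outdir, cached = TRUE),
      class = "patient_report"
    )))
  }
  cfg <- bundle$config
  cohort <- bundle$cohort
  tumor_samples <- setdiff(cohort$samples$sample, "normal")
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("patient=", bundle$patient_id, " seed=", cfg$seed,
       " n_tumor_samples=", length(tumor_samples))

  # --- strict filtering ------------------------------------------------------
  filtered <- apply_strict_filters(cohort$calls, cfg$filters)
  rejections <- filter_rejections(filtered)
  note("filter: ", nrow(cohort$calls), " in, ", nrow(filtered), " retained, ",
       nrow(rejections), " rejected")

  # --- purity ---------------------------------------------------------------
  purity <- purrr::map_dfr(tumor_samples, function(s) {
    v <- filtered$vaf[filtered$sample == s]
    out <- tryCatch(estimate_purity(v, min_sites = 20,
                                    flag_below = cfg$min_purity),
                    error = function(e) {
                      tibble::tibble(purity = NA_real_, n_sites = length(v),
                                     flagged = TRUE)
                    })
    dplyr::mutate(out, sample = s, .before = 1)
  })

  # --- clonality ------------------------------------------------------------
  exclusions <- tibble::tibble(sample = character(), stage = character(),
                               reason = character())
  shared <- NULL; tree <- NULL; overlaps <- NULL
  is_snv <- if ("variant_type" %in% names(filtered)) {
    filtered$variant_type != "indel"
  } else rep(TRUE, nrow(filtered))
  snv_samples <- tumor_samples[vapply(tumor_samples, function(s) {
    sum(filtered$sample == s & is_snv) > 0
  }, logical(1))]
  if (length(snv_samples) >= 2) {
    shared <- pairwise_shared(filtered[filtered$sample %in% snv_samples, ])
    mat <- build_character_matrix(filtered[filtered$sample %in% snv_samples, ])
    if (nrow(mat) >= 4) {
      tree <- search_mp_tree(mat, exhaustive_max = cfg$exhaustive_max)
      tree <- assign_branch_counts(tree, mat)
      tree <- bootstrap_support(mat, n_reps = cfg$bootstrap_reps,
                                seed = cfg$seed, tree = tree,
                                exhaustive_max = cfg$exhaustive_max)
      note("tree: score=", tree$score, " reps=", cfg$bootstrap_reps)
    }
    overlaps <- classify_pair_overlaps(shared, filtered, cfg)
  } else {
    note("clonality skipped: fewer than 2 tumor samples with SNVs")
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      sample = tumor_samples, stage = "clonality",
      reason = "fewer than 2 tumor samples"
    ))
  }

  # --- signatures -----------------------------------------------------------
  signature_loadings <- purrr::map_dfr(tumor_samples, function(s) {
    sub <- filtered[filtered$sample == s, , drop = FALSE]
    if (nrow(sub) == 0 || !"context" %in% names(sub)) {
      return(tibble::tibble(sample = s, signature = character(),
                            loading = numeric()))
    }
    prof <- suppressWarnings(count_96(sub))
    if (sum(prof) == 0) {
      return(tibble::tibble(sample = s, signature = character(),
                            loading = numeric()))
    }
    fit <- fit_signatures(prof, bundle$signatures)
    dplyr::mutate(tidy(fit)[tidy(fit)$active, c("signature", "loading")],
                  sample = s, .before = 1)
  })

  # --- copy number + phasing ------------------------------------------------
  cna <- run_cna_stage(cohort, tumor_samples, cfg, shared, note)

  report <- structure(
    list(
      patient_id = bundle$patient_id,
      samples = cohort$samples,
      filtered_calls = filtered,
      rejections = rejections,
      purity = purity,
      shared = shared,
      tree = tree,
      overlaps = overlaps,
      signature_loadings = signature_loadings,
      segments = cna$segments,
      whole_chrom_events = cna$events,
      chromothripsis = cna$chromothripsis,
      phasing = cna$phasing,
      concordance = cna$concordance,
      exclusions = exclusions,
      log = log_lines
    ),
    class = "patient_report"
  )
  if (!is.null(outdir)) write_patient_report(report, outdir)
  report
}

# Classify every sample pair with a non-empty strict overlap.
classify_pair_overlaps <- function(shared, filtered, cfg) {
  pairs <- tidy(shared)
  pairs <- pairs[pairs$shared > 0, , drop = FALSE]
  key_all <- variant_key(filtered$chrom, filtered$pos, filtered$ref,
                         filtered$alt)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$sample_a[i]; b <- pairs$sample_b[i]
    keys <- shared_variants(shared, a, b)
    sel <- key_all %in% keys & filtered$sample %in% c(a, b)
    sv <- tibble::tibble(
      sample = filtered$sample[sel],
      vaf = filtered$vaf[sel],
      key = key_all[sel]
    )
    oc <- classify_overlap(sv, min_trunk = cfg$min_trunk,
                           clonal_floor = cfg$clonal_floor,
                           trace_ceiling = cfg$trace_ceiling,
                           embryonic_max = cfg$embryonic_max)
    tibble::tibble(sample_a = a, sample_b = b, n_shared = oc$n_shared,
                   label = oc$label)
  })
}

run_cna_stage <- function(cohort, tumor_samples, cfg, shared, note) {
  if (is.null(cohort$windows) || nrow(cohort$windows) == 0) {
    return(list(segments = NULL, events = NULL, chromothripsis = NULL,
                phasing = NULL, concordance = NULL))
  }
  chrom_lengths <- cohort$windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(length = max(.data$end), .groups = "drop")
  segments <- purrr::map_dfr(tumor_samples, function(s) {
    dplyr::mutate(
      segment_logratio(cohort$windows, paste0("count_", s)),
      sample = s, .before = 1
    )
  })
  events <- purrr::map_dfr(tumor_samples, function(s) {
    purrr::map_dfr(chrom_lengths$chrom, function(cc) {
      seg <- segments[segments$sample == s & segments$chrom == cc, ]
      ev <- call_whole_chrom(seg, chrom_lengths$length[chrom_lengths$chrom == cc],
                             min_fraction = cfg$whole_chrom_fraction)
      if (nrow(ev) > 0) dplyr::mutate(ev, sample = s, .before = 1) else ev
    })
  })
  chromo <- purrr::map_dfr(tumor_samples, function(s) {
    purrr::map_dfr(chrom_lengths$chrom, function(cc) {
      seg <- segments[segments$sample == s & segments$chrom == cc, ]
      dplyr::mutate(detect_chromothripsis(seg), sample = s, .before = 1)
    })
  })
  note("cna: ", nrow(events), " whole-chromosome events, ",
       sum(chromo$positive), " chromothripsis-positive chromosomes")

  phasing <- NULL; concordance <- NULL
  if (!is.null(shared) && nrow(events) > 0) {
    # reference sample: the inferred metastatic primary = the sample with
    # the largest summed shared-SNV count
    off <- shared$counts
    diag(off) <- 0L
    ref <- shared$samples[which.max(rowSums(off))]
    related <- shared$samples[off[ref, ] >= cfg$min_trunk]
    phasing <- purrr::map_dfr(related, function(s) {
      purrr::map_dfr(unique(events$chrom), function(cc) {
        has_ref <- any(events$sample == ref & events$chrom == cc)
        has_test <- any(events$sample == s & events$chrom == cc)
        if (!has_ref || !has_test) return(tibble::tibble())
        pc <- phase_event(
          cohort$het_snps[cohort$het_snps$chrom == cc, ], ref, s,
          delta = cfg$phase_delta,
          concordance_threshold = cfg$phase_concordance,
          min_snps = cfg$phase_min_snps
        )
        dplyr::mutate(glance(pc), chrom = cc,
                      kind = events$kind[events$sample == s &
                                           events$chrom == cc][1],
                      .before = 1)
      })
    })
    if (!is.null(phasing) && nrow(phasing) > 0) {
      mono <- phasing[phasing$kind == "loss" &
                        phasing$homolog_call %in%
                        c("same_as_reference", "different_from_reference"), ]
      if (nrow(mono) > 0) {
        concordance <- concordance_binomial_test(
          sum(mono$homolog_call == "same_as_reference"), nrow(mono)
        )
      }
    }
  }
  list(segments = segments, events = events, chromothripsis = chromo,
       phasing = phasing, concordance = concordance)
}

write_patient_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      readr::write_tsv(x, file.path(outdir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  wr(report$purity, "purity")
  wr(report$rejections, "rejections")
  wr(report$overlaps, "overlaps")
  wr(report$signature_loadings, "signature_loadings")
  wr(report$segments, "segments")
  wr(report$whole_chrom_events, "whole_chrom_events")
  wr(report$chromothripsis, "chromothripsis")
  wr(report$phasing, "phasing")
  if (!is.null(report$shared)) {
    counts <- tibble::as_tibble(report$shared$counts, rownames = "sample")
    readr::write_tsv(counts, file.path(outdir, "shared_matrix.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$tree)) {
    export_newick(report$tree, file.path(outdir, "tree.nwk"))
  }
  writeLines(report$log, file.path(outdir, "run.log"))
  writeLines(format(Sys.time()), file.path(outdir, "report_complete"))
  invisible(outdir)
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> patient ", x$patient_id, "\n", sep = "")
  for (line in x$log %||% character(0)) cat("  ", line, "\n", sep = "")
  invisible(x)
}

#' Run a cohort of patients and pool the homolog-concordance test
#'
#' @param bundles list of [patient_bundle()] objects with unique ids.
#' @param outdir optional root directory (per-patient subdirectories).
#' @param force passed to [run_patient()].
#' @return list of class `cohort_summary`: per-patient reports, a pooled
#'   exact binomial concordance test over all related monoallelic pairs
#'   (or `NULL` when none exist), and a per-sample summary table of SNV
#'   burdens and signature loadings.
#' @export
run_cohort <- function(bundles, outdir = NULL, force = FALSE) {
  ids <- vapply(bundles, function(b) b$patient_id, character(1))
  if (anyDuplicated(ids)) {
    abort("duplicate patient ids", class = "mfclone_input_error")
  }
  reports <- lapply(bundles, function(b) {
    run_patient(b, outdir = if (is.null(outdir)) NULL else
      file.path(outdir, b$patient_id), force = force)
  })
  names(reports) <- ids
  n_conc <- 0L; n_tot <- 0L
  for (r in reports) {
    if (!is.null(r$concordance)) {
      n_conc <- n_conc + r$concordance$n_concordant
      n_tot <- n_tot + r$concordance$n_total
    }
  }
  pooled <- if (n_tot > 0) concordance_binomial_test(n_conc, n_tot) else NULL
  burden <- purrr::map_dfr(reports, function(r) {
    if (is.null(r$filtered_calls)) return(tibble::tibble())
    b <- r$filtered_calls |>
      dplyr::count(.data$sample, name = "snv_burden")
    dplyr::mutate(b, patient = r$patient_id, .before = 1)
  })
  loadings <- purrr::map_dfr(reports, function(r) {
    if (is.null(r$signature_loadings)) return(tibble::tibble())
    dplyr::mutate(r$signature_loadings, patient = r$patient_id, .before = 1)
  })
  structure(
    list(reports = reports, pooled_concordance = pooled,
         burdens = burden, signature_loadings = loadings),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", length(x$reports), " patient(s)\n", sep = "")
  if (!is.null(x$pooled_concordance)) print(x$pooled_concordance)
  else cat("  homolog concordance test: not applicable (no informative pairs)\n")
  invisible(x)
}
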