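#' Declare a ground-truth copy-number event for simulation
#'
#' @param chrom chromosome name (must exist in the simulation genome).
#' @param kind `"loss"` or `"gain"`.
#' @param homolog which parental homolog is affected: `"A"`, `"B"`, or
#'   `"both"` (biallelic; only meaningful for losses).
#' @param carriers character vector of carrier sample ids (non-empty).
#' @param start,end optional 0-based half-open interval; both `NULL` means
#'   the whole chromosome.
#' @return A list of class `truth_cna`.
#' @export
truth_cna <- function(chrom, kind = c("loss", "gain"), homolog = c("A", "B", "both"),
                      carriers, start = NULL, end = NULL) {
  kind <- match.arg(kind)
  homolog <- match.arg(homolog)
  if (length(carriers) < 1) abort("`carriers` must be non-empty")
  if (xor(is.null(start), is.null(end))) {
    abort("`start` and `end` must be given together")
  }
  structure(
    list(chrom = chrom, kind = kind, homolog = homolog,
         carriers = carriers, start = start, end = end),
    class = "truth_cna"
  )
}

#' Configure a synthetic multifocal tumor cohort
#'
#' Defines one simulated patient: several clonally independent primary
#' tumors, of which one (or more) seeds a set of metastases that inherit the
#' seeding primary's trunk mutations. Every sample additionally carries
#' private mutations; optional early-developmental (embryonic) variant sets
#' and sample-handling cross-contamination can be injected. Defaults follow
#' the archetype of a multifocal small-intestine neuroendocrine tumor
#' patient: six independent primaries (A–F) of which C seeds five metastases
#' (G–K) through a 667-variant clonal trunk, with 300–1,700 private SNVs per
#' sample, ~40x coverage, clock-like SBS5 spectra and 60% tumor purity.
#'
#' @param n_primaries number of primary tumors (named A, B, C, ...).
#' @param metastatic_primary_ids sample ids of primaries that seed metastases.
#' @param n_mets_per_seed metastases per seeding primary.
#' @param trunk_sizes trunk SNV count per seeding primary (recycled).
#' @param private_range `c(min, max)` private SNVs per sample (uniform draw).
#' @param embryonic_shared list of `list(samples =, count =)` early-lineage
#'   variant sets, emitted at clonal VAF in every listed sample.
#' @param contamination list of `list(donor =, recipient =, count =,
#'   trace_vaf = c(lo, hi))` cross-contamination events: `count` of the
#'   donor's clonal variants appear in the recipient at trace allele
#'   fraction drawn from `trace_vaf`.
#' @param purity tumor purity in (0, 1]; scalar or named per tumor sample.
#' @param depth mean sequencing coverage.
#' @param genome a [genome_model()].
#' @param signatures signature definition matrix (96 x k).
#' @param signature_mix named loadings over `colnames(signatures)`; need not
#'   be normalised (it is renormalised to sum to 1).
#' @param cna_events list of [truth_cna()] events.
#' @param het_snp_spacing mean spacing (bp) between germline het SNPs.
#' @param window_size read-count window width in bp (0-based half-open).
#' @param indel_rate fraction of additional private calls emitted as a
#'   labelled indel minority class (no sequence realism).
#' @param noise logical; `TRUE` draws per-site depth from Poisson and alt
#'   reads from Binomial with a two-read detection floor, `FALSE` emits
#'   deterministic expected values.
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome = genome_model(chroms = c("chr1", "chr2")))
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_primaries = 6, metastatic_primary_ids = "C",
                       n_mets_per_seed = 5, trunk_sizes = 667,
                       private_range = c(300, 1700),
                       embryonic_shared = list(), contamination = list(),
                       purity = 0.6, depth = 40,
                       genome = genome_model(),
                       signatures = synthetic_signature_matrix(),
                       signature_mix = c(SBS5 = 1),
                       cna_events = list(),
                       het_snp_spacing = 2000, window_size = 2000,
                       indel_rate = 0.02, noise = TRUE, seed = 1L) {
  if (n_primaries < 1) abort("`n_primaries` must be >= 1")
  primaries <- make_sample_ids(n_primaries)
  if (!all(metastatic_primary_ids %in% primaries)) {
    abort("`metastatic_primary_ids` must be a subset of the primary ids",
          class = "mfclone_config_error")
  }
  trunk_sizes <- rep_len(trunk_sizes, length(metastatic_primary_ids))
  if (length(metastatic_primary_ids) > 0 && any(trunk_sizes <= 0)) {
    abort("`trunk_sizes` must be positive for each metastatic primary",
          class = "mfclone_config_error")
  }
  if (length(private_range) != 2 || private_range[1] > private_range[2]) {
    abort("`private_range` must be c(min, max) with min <= max",
          class = "mfclone_config_error")
  }
  n_mets_total <- length(metastatic_primary_ids) * n_mets_per_seed
  mets <- make_sample_ids(n_primaries + n_mets_total)[
    seq_len(n_mets_total) + n_primaries
  ]
  tumor_samples <- c(primaries, mets)
  purity <- normalize_purity(purity, tumor_samples)
  if (any(purity <= 0) || any(purity > 1)) {
    abort("purities must lie in (0, 1]", class = "mfclone_config_error")
  }
  if (is.null(names(signature_mix)) ||
      !all(names(signature_mix) %in% colnames(signatures))) {
    abort("`signature_mix` names must match signature matrix columns",
          class = "mfclone_config_error")
  }
  signature_mix <- signature_mix / sum(signature_mix)
  for (ev in cna_events) {
    if (!inherits(ev, "truth_cna")) abort("`cna_events` must be truth_cna objects")
    len <- genome$chromosomes$length[genome$chromosomes$chrom == ev$chrom]
    if (length(len) != 1) {
      abort(paste0("CNA chromosome ", ev$chrom, " not in genome model"),
            class = "mfclone_config_error")
    }
    if (!is.null(ev$start) && (ev$start < 0 || ev$end > len || ev$end <= ev$start)) {
      abort("CNA interval outside chromosome", class = "mfclone_config_error")
    }
    if (!all(ev$carriers %in% tumor_samples)) {
      abort("CNA carriers must be cohort samples", class = "mfclone_config_error")
    }
  }
  for (em in embryonic_shared) {
    if (!all(em$samples %in% tumor_samples)) {
      abort("embryonic sample set must be cohort samples",
            class = "mfclone_config_error")
    }
  }
  for (cn in contamination) {
    if (!all(c(cn$donor, cn$recipient) %in% tumor_samples)) {
      abort("contamination donor/recipient must be cohort samples",
            class = "mfclone_config_error")
    }
  }
  structure(
    list(
      primaries = primaries, mets = mets,
      metastatic_primary_ids = metastatic_primary_ids,
      n_mets_per_seed = n_mets_per_seed, trunk_sizes = trunk_sizes,
      private_range = private_range, embryonic_shared = embryonic_shared,
      contamination = contamination, purity = purity, depth = depth,
      genome = genome, signatures = signatures, signature_mix = signature_mix,
      cna_events = cna_events, het_snp_spacing = het_snp_spacing,
      window_size = window_size, indel_rate = indel_rate,
      noise = noise, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

make_sample_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else {
    c(LETTERS, paste0("S", seq_len(n - 26)))
  }
}

normalize_purity <- function(purity, samples) {
  if (is.null(names(purity))) {
    setNames(rep_len(purity, length(samples)), samples)
  } else {
    if (!all(samples %in% names(purity))) {
      abort("named `purity` must cover every tumor sample",
            class = "mfclone_config_error")
    }
    purity[samples]
  }
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw somatic mutations under a signature mixture
#'
#' Samples `n` single-base substitutions whose 96-channel classes follow the
#' mixture of signature probability vectors given by `signature_mix`, placed
#' uniformly on the genome model's chromosomes (length-weighted, unique
#' positions within a call). Half of the mutations are reported on the
#' purine strand, as real callers do; the `channel` column always gives the
#' canonical pyrimidine-strand class.
#'
#' Uses the current RNG stream; seed upstream for reproducibility.
#'
#' @param n number of mutations (>= 0).
#' @param signature_mix named loadings over columns of `signatures`.
#' @param genome a [genome_model()].
#' @param signatures 96-row signature matrix.
#' @return tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `context` (trinucleotide as sequenced), `channel`.
#' @export
draw_mutations <- function(n, signature_mix, genome = genome_model(),
                           signatures = synthetic_signature_matrix()) {
  if (n < 0) abort("`n` must be >= 0")
  ch <- sbs96_channels()
  if (is.null(names(signature_mix)) ||
      !all(names(signature_mix) %in% colnames(signatures))) {
    abort("unknown signature name in `signature_mix`",
          class = "mfclone_config_error")
  }
  if (n == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), context = character(), channel = character()
    ))
  }
  mix <- signature_mix / sum(signature_mix)
  probs <- as.numeric(signatures[, names(mix), drop = FALSE] %*% mix)
  idx <- sample.int(96, n, replace = TRUE, prob = probs)
  chrom_tbl <- genome$chromosomes
  ci <- sample.int(nrow(chrom_tbl), n, replace = TRUE, prob = chrom_tbl$length)
  pos <- as.integer(ceiling(runif(n) * chrom_tbl$length[ci]))
  # enforce unique (chrom, pos) within this draw
  key <- paste0(chrom_tbl$chrom[ci], ":", pos)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    pos[dup] <- as.integer(ceiling(runif(length(dup)) * chrom_tbl$length[ci[dup]]))
    key <- paste0(chrom_tbl$chrom[ci], ":", pos)
  }
  five <- ch$five[idx]; three <- ch$three[idx]
  ref <- ch$ref[idx]; alt <- ch$alt[idx]
  context <- paste0(five, ref, three)
  flip <- runif(n) < 0.5
  if (any(flip)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    context[flip] <- revcomp(context[flip])
    ref[flip] <- comp[ref[flip]]
    alt[flip] <- comp[alt[flip]]
  }
  tibble::tibble(
    chrom = chrom_tbl$chrom[ci], pos = pos, ref = ref, alt = alt,
    context = context, channel = ch$channel[idx]
  )
}

#' Simulate a multifocal tumor cohort with full ground truth
#'
#' Generates one patient's worth of data under a [sim_config()]: per-sample
#' somatic call tables, a germline heterozygous-SNP table with per-sample
#' VAFs, fixed-window read-count tables for copy-number analysis, and a
#' machine-readable truth record (variant lineages, true VAFs, CNA homolog
#' labels, SNP phase, and the seeding structure).
#'
#' Metastases carry their seeding primary's trunk variants plus private
#' variants; non-metastatic primaries share nothing except configured
#' embryonic sets or contamination. Observed alt-read counts are drawn
#' binomially at Poisson per-site depth with expected VAF scaled by purity
#' and local copy number; calls with fewer than two supporting reads are
#' dropped (the caller support floor). Contamination variants in the
#' recipient are drawn conditional on that floor, emulating the relaxed
#' caller's output in which a reported trace variant by definition has
#' supporting reads.
#'
#' @param config a [sim_config()].
#' @return A list of class `mf_cohort` with elements `config`, `samples`
#'   (tibble: sample, role, purity), `calls` (long tibble of somatic calls),
#'   `het_snps` (wide tibble), `windows` (wide tibble), and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  tumor_samples <- c(cfg$primaries, cfg$mets)
  roles <- c(
    rep("primary", length(cfg$primaries)),
    unlist(lapply(seq_along(cfg$metastatic_primary_ids), function(i) {
      n <- cfg$n_mets_per_seed
      c(rep("lymph_node_met", min(3, n)), rep("peritoneal_met", max(0, n - 3)))
    }))
  )
  samples <- tibble::tibble(
    sample = c(tumor_samples, "normal"),
    role = c(roles, "blood_normal"),
    purity = c(unname(cfg$purity), NA_real_)
  )
  seeded_by <- tibble::tibble(
    sample = cfg$mets,
    seeded_by = rep(cfg$metastatic_primary_ids, each = cfg$n_mets_per_seed)
  )

  # ---- lineage bookkeeping -------------------------------------------------
  lineages <- list()
  for (i in seq_along(cfg$metastatic_primary_ids)) {
    seedp <- cfg$metastatic_primary_ids[i]
    carriers <- c(seedp, seeded_by$sample[seeded_by$seeded_by == seedp])
    lineages[[length(lineages) + 1]] <- list(
      lineage = "trunk", lineage_id = paste0("trunk_", seedp),
      n = cfg$trunk_sizes[i], carriers = carriers, vaf_kind = "clonal"
    )
  }
  n_priv <- round(runif(length(tumor_samples),
                        cfg$private_range[1], cfg$private_range[2]))
  for (j in seq_along(tumor_samples)) {
    lineages[[length(lineages) + 1]] <- list(
      lineage = "private", lineage_id = paste0("private_", tumor_samples[j]),
      n = n_priv[j], carriers = tumor_samples[j], vaf_kind = "clonal"
    )
  }
  for (k in seq_along(cfg$embryonic_shared)) {
    em <- cfg$embryonic_shared[[k]]
    lineages[[length(lineages) + 1]] <- list(
      lineage = "embryonic", lineage_id = paste0("embryonic_", k),
      n = em$count, carriers = em$samples, vaf_kind = "clonal"
    )
  }
  for (k in seq_along(cfg$contamination)) {
    cn <- cfg$contamination[[k]]
    lineages[[length(lineages) + 1]] <- list(
      lineage = "contamination", lineage_id = paste0("contamination_", k),
      n = cn$count, carriers = c(cn$donor, cn$recipient),
      vaf_kind = "contamination", donor = cn$donor, recipient = cn$recipient,
      trace_vaf = cn$trace_vaf
    )
  }

  n_total <- sum(vapply(lineages, function(l) l$n, numeric(1)))
  muts <- draw_mutations(n_total, cfg$signature_mix, cfg$genome, cfg$signatures)
  muts$variant_type <- "SNV"
  muts$lineage <- rep(
    vapply(lineages, function(l) l$lineage, character(1)),
    vapply(lineages, function(l) l$n, numeric(1))
  )
  muts$lineage_id <- rep(
    vapply(lineages, function(l) l$lineage_id, character(1)),
    vapply(lineages, function(l) l$n, numeric(1))
  )

  # labelled indel minority class, private per sample, no sequence realism
  n_indel <- round(cfg$indel_rate * n_priv)
  if (sum(n_indel) > 0) {
    ind <- draw_mutations(sum(n_indel), cfg$signature_mix, cfg$genome,
                          cfg$signatures)
    ind$variant_type <- "indel"
    del <- runif(nrow(ind)) < 0.5
    ind$ref <- ifelse(del, paste0(ind$ref, "A"), ind$ref)
    ind$alt <- ifelse(del, substr(ind$ref, 1, 1), paste0(ind$alt, "T"))
    ind$context <- NA_character_
    ind$channel <- NA_character_
    ind$lineage <- "private"
    ind$lineage_id <- rep(paste0("private_", tumor_samples), n_indel)
    muts <- dplyr::bind_rows(muts, ind)
  }

  carriers_of <- setNames(
    lapply(lineages, function(l) l$carriers),
    vapply(lineages, function(l) l$lineage_id, character(1))
  )

  # ---- expected VAFs per (variant, carrier) --------------------------------
  long <- muts |>
    dplyr::mutate(.lid = .data$lineage_id) |>
    dplyr::mutate(sample = unname(carriers_of[.data$.lid])) |>
    tidyr::unnest_longer("sample") |>
    dplyr::select(-".lid")
  long$purity <- cfg$purity[long$sample]
  cn <- local_copy_number(long$chrom, long$pos, long$sample, cfg$cna_events)
  long$expected_vaf <- long$purity / ((1 - long$purity) * 2 + long$purity * cn)
  # trace contamination overrides the clonal expectation in the recipient
  for (k in seq_along(cfg$contamination)) {
    cnk <- cfg$contamination[[k]]
    sel <- long$lineage_id == paste0("contamination_", k) &
      long$sample == cnk$recipient
    long$expected_vaf[sel] <- runif(sum(sel), cnk$trace_vaf[1], cnk$trace_vaf[2])
  }
  truth_vafs <- long |>
    dplyr::select("sample", "chrom", "pos", "ref", "alt", true_vaf = "expected_vaf")

  # ---- observation model ---------------------------------------------------
  m <- nrow(long)
  if (cfg$noise) {
    long$depth_site <- rpois(m, cfg$depth)
    long$alt_reads <- rbinom(m, long$depth_site, pmin(long$expected_vaf, 1))
    cond <- long$lineage == "contamination" & long$sample %in%
      vapply(cfg$contamination, function(x) x$recipient, character(1))
    # conditional-on-detection draw for trace variants (see Details)
    redo <- which(cond & long$alt_reads < 2)
    tries <- 0
    while (length(redo) > 0 && tries < 200) {
      long$depth_site[redo] <- rpois(length(redo), cfg$depth)
      long$alt_reads[redo] <- rbinom(length(redo), long$depth_site[redo],
                                     pmin(long$expected_vaf[redo], 1))
      redo <- which(cond & long$alt_reads < 2)
      tries <- tries + 1
    }
    if (length(redo) > 0) {
      long$alt_reads[redo] <- 2L
      long$depth_site[redo] <- pmax(long$depth_site[redo], 2L)
    }
    long$alt_fwd <- rbinom(m, long$alt_reads, 0.5)
    long$normal_depth <- rpois(m, cfg$depth)
  } else {
    long$depth_site <- rep(as.integer(round(cfg$depth)), m)
    long$alt_reads <- as.integer(round(long$expected_vaf * long$depth_site))
    long$alt_fwd <- long$alt_reads %/% 2L
    long$normal_depth <- long$depth_site
  }
  long$alt_rev <- long$alt_reads - long$alt_fwd
  long <- long[long$alt_reads >= 2, , drop = FALSE]
  long$vaf <- long$alt_reads / pmax(long$depth_site, 1)
  # caller provenance: the sensitive caller reports every emitted record;
  # the second caller misses weakly supported subclonal sites
  both <- long$alt_reads >= 3 & long$vaf >= 0.05
  long$caller_set <- ifelse(both, "mutect2,varscan", "varscan")
  long$in_normal <- FALSE
  long$population_flag <- FALSE

  calls <- long |>
    dplyr::select(
      "sample", "chrom", "pos", "ref", "alt", "variant_type", "context",
      "vaf", depth = "depth_site", "alt_fwd", "alt_rev", "normal_depth",
      "in_normal", "caller_set", "population_flag"
    ) |>
    dplyr::arrange(.data$sample, .data$chrom, .data$pos, .data$alt)

  het <- simulate_het_snps(cfg, tumor_samples)
  win <- simulate_windows(cfg, tumor_samples)

  cna_truth <- purrr::map_dfr(cfg$cna_events, function(ev) {
    len <- cfg$genome$chromosomes$length[cfg$genome$chromosomes$chrom == ev$chrom]
    tibble::tibble(
      chrom = ev$chrom, kind = ev$kind, homolog = ev$homolog,
      start = ifelse(is.null(ev$start), 0L, ev$start),
      end = ifelse(is.null(ev$end), len, ev$end),
      sample = ev$carriers
    )
  })

  structure(
    list(
      config = cfg, samples = samples, calls = calls,
      het_snps = het$table, windows = win,
      truth = list(
        variants = muts |>
          dplyr::mutate(carriers = unname(carriers_of[.data$lineage_id])),
        vafs = truth_vafs,
        cna = cna_truth,
        snp_phase = het$phase,
        tree = seeded_by
      )
    ),
    class = "mf_cohort"
  )
}

# Tumor-cell copy number at (chrom, pos) for each sample given truth CNAs.
local_copy_number <- function(chrom, pos, sample, events) {
  cn <- rep(2, length(chrom))
  for (ev in events) {
    hit <- chrom == ev$chrom & sample %in% ev$carriers
    if (!is.null(ev$start)) hit <- hit & pos > ev$start & pos <= ev$end
    delta <- switch(ev$kind, loss = -1, gain = 1)
    if (ev$homolog == "both") delta <- 2 * delta
    cn[hit] <- cn[hit] + delta
  }
  pmax(cn, 0)
}

simulate_het_snps <- function(cfg, tumor_samples) {
  chroms <- cfg$genome$chromosomes
  n_per <- pmax(1L, as.integer(round(chroms$length / cfg$het_snp_spacing)))
  chrom <- rep(chroms$chrom, n_per)
  len <- rep(chroms$length, n_per)
  pos <- as.integer(ceiling(runif(length(chrom)) * len))
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  keep <- !duplicated(paste0(chrom, ":", pos))
  chrom <- chrom[keep]; pos <- pos[keep]
  n <- length(chrom)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  alt_hom <- sample(c("A", "B"), n, replace = TRUE)

  tab <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = unname(alt))
  if (cfg$noise) {
    dn <- rpois(n, cfg$depth)
    tab$vaf_normal <- rbinom(n, dn, 0.5) / pmax(dn, 1)
    tab$depth_normal <- dn
  } else {
    tab$vaf_normal <- 0.5
    tab$depth_normal <- as.integer(round(cfg$depth))
  }
  for (s in tumor_samples) {
    p <- cfg$purity[[s]]
    vaf_true <- rep(0.5, n)
    for (ev in cfg$cna_events) {
      if (!(s %in% ev$carriers)) next
      hit <- chrom == ev$chrom
      if (!is.null(ev$start)) hit <- hit & pos > ev$start & pos <= ev$end
      if (ev$homolog == "both") next # biallelic: tumor contributes nothing, VAF stays 0.5
      on_ev <- hit & alt_hom == ev$homolog
      off_ev <- hit & alt_hom != ev$homolog
      if (ev$kind == "loss") {
        vaf_true[on_ev] <- (1 - p) / (2 - p)
        vaf_true[off_ev] <- 1 / (2 - p)
      } else {
        vaf_true[on_ev] <- (1 + p) / (2 + p)
        vaf_true[off_ev] <- 1 / (2 + p)
      }
    }
    if (cfg$noise) {
      ds <- rpois(n, cfg$depth)
      tab[[paste0("vaf_", s)]] <- rbinom(n, ds, vaf_true) / pmax(ds, 1)
      tab[[paste0("depth_", s)]] <- ds
    } else {
      tab[[paste0("vaf_", s)]] <- vaf_true
      tab[[paste0("depth_", s)]] <- as.integer(round(cfg$depth))
    }
  }
  list(
    table = tab,
    phase = tibble::tibble(chrom = chrom, pos = pos, alt_homolog = alt_hom)
  )
}

simulate_windows <- function(cfg, tumor_samples) {
  chroms <- cfg$genome$chromosomes
  win <- purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
    starts <- seq(0L, chroms$length[i] - 1L, by = cfg$window_size)
    tibble::tibble(
      chrom = chroms$chrom[i], start = starts,
      end = pmin(starts + cfg$window_size, chroms$length[i])
    )
  })
  n <- nrow(win)
  # expected reads per window at 100 bp effective read length
  lambda0 <- cfg$depth * (win$end - win$start) / 100
  win$count_normal <- if (cfg$noise) rpois(n, lambda0) else as.integer(round(lambda0))
  mid <- (win$start + win$end) / 2
  for (s in tumor_samples) {
    p <- cfg$purity[[s]]
    cn <- local_copy_number(win$chrom, mid, rep(s, n), cfg$cna_events)
    lam <- lambda0 * ((1 - p) * 2 + p * cn) / 2
    win[[paste0("count_", s)]] <- if (cfg$noise) rpois(n, lam) else as.integer(round(lam))
  }
  win
}

#' @export
print.mf_cohort <- function(x, ...) {
  cat("<mf_cohort> ", nrow(x$samples) - 1, " tumor samples + normal; ",
      nrow(x$truth$variants), " true somatic variants; ",
      nrow(x$calls), " emitted calls\n", sep = "")
  invisible(x)
}
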