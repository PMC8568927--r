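#' Segment tumor/normal window read-count log-ratios
#'
#' Computes per-window log2 tumor/normal depth ratios (library-size
#' normalised) and segments each chromosome by recursive binary splitting:
#' the split maximising the mean difference between the two sides is
#' accepted while that difference is at least `min_delta` and both sides
#' keep `min_windows` windows. Segment states are assigned by thresholds on
#' the segment mean log2-ratio. Segments tile each chromosome exactly; use
#' [filter_small_segments()] for the small-segment reporting filter.
#'
#' @param windows tibble with `chrom`, `start`, `end` (0-based half-open,
#'   uniform, sorted, non-overlapping) and the two count columns.
#' @param tumor_col,normal_col names of the tumor and normal count columns.
#' @param min_windows minimum windows per segment (default 5).
#' @param min_delta minimum mean log2-ratio difference to accept a split.
#' @param loss_threshold,gain_threshold state thresholds on the segment
#'   mean log2-ratio (defaults -0.25 / 0.2: symmetric detection of
#'   hemizygous events down to ~30% purity).
#' @param recenter subtract the genome-wide median log2-ratio so the
#'   copy-neutral state sits at 0 (default TRUE; assumes most of the
#'   genome is neutral).
#' @return tibble of segments: `chrom`, `start`, `end`, `n_windows`,
#'   `log2_ratio`, `state` (`loss`/`neutral`/`gain`).
#' @export
segment_logratio <- function(windows, tumor_col, normal_col = "count_normal",
                             min_windows = 5, min_delta = 0.25,
                             loss_threshold = -0.25, gain_threshold = 0.2,
                             recenter = TRUE) {
  need <- c("chrom", "start", "end", tumor_col, normal_col)
  missing <- setdiff(need, names(windows))
  if (length(missing) > 0) {
    abort(paste0("windows table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mfclone_input_error")
  }
  windows <- dplyr::arrange(windows, .data$chrom, .data$start)
  by_chr <- split(windows, windows$chrom)
  for (w in by_chr) {
    if (any(w$end <= w$start) || any(diff(w$start) < (w$end - w$start)[-nrow(w)])) {
      abort("window grid must be sorted and non-overlapping within chromosomes",
            class = "mfclone_input_error")
    }
  }
  t_tot <- sum(windows[[tumor_col]])
  n_tot <- sum(windows[[normal_col]])
  lr_all <- log2(((windows[[tumor_col]] + 0.5) / t_tot) /
                   ((windows[[normal_col]] + 0.5) / n_tot))
  if (recenter) {
    # anchor the copy-neutral state at log2-ratio 0: library-size
    # normalisation alone shifts the baseline when a sizable genome
    # fraction is altered; assumes most windows are neutral
    lr_all <- lr_all - median(lr_all)
  }

  seg_one <- function(idx) {
    lr <- lr_all[idx]
    n <- length(lr)
    segments <- list()
    rec <- function(lo, hi) {
      len <- hi - lo + 1
      if (len >= 2 * min_windows) {
        x <- lr[lo:hi]
        cs <- cumsum(x)
        tot <- cs[len]
        b <- seq(min_windows, len - min_windows)
        delta <- abs(cs[b] / b - (tot - cs[b]) / (len - b))
        bi <- which.max(delta)
        if (delta[bi] >= min_delta) {
          rec(lo, lo + b[bi] - 1)
          rec(lo + b[bi], hi)
          return(invisible())
        }
      }
      segments[[length(segments) + 1]] <<- c(lo, hi)
      invisible()
    }
    rec(1, n)
    bounds <- do.call(rbind, segments)
    # merge adjacent fragments whose means no longer differ by min_delta
    # (binary splitting can strand sub-threshold pieces inside a block)
    repeat {
      if (nrow(bounds) < 2) break
      means <- vapply(seq_len(nrow(bounds)), function(i) {
        mean(lr[bounds[i, 1]:bounds[i, 2]])
      }, numeric(1))
      d <- abs(diff(means))
      j <- which.min(d)
      if (d[j] >= min_delta) break
      bounds[j, 2] <- bounds[j + 1, 2]
      bounds <- bounds[-(j + 1), , drop = FALSE]
    }
    bounds
  }

  out <- purrr::map_dfr(by_chr, function(w) {
    idx <- match(paste(w$chrom, w$start), paste(windows$chrom, windows$start))
    bounds <- seg_one(idx)
    tibble::tibble(
      chrom = w$chrom[1],
      start = w$start[bounds[, 1]],
      end = w$end[bounds[, 2]],
      n_windows = bounds[, 2] - bounds[, 1] + 1,
      log2_ratio = vapply(seq_len(nrow(bounds)), function(i) {
        mean(lr_all[idx[bounds[i, 1]:bounds[i, 2]]])
      }, numeric(1))
    )
  })
  out$state <- dplyr::case_when(
    out$log2_ratio < loss_threshold ~ "loss",
    out$log2_ratio > gain_threshold ~ "gain",
    TRUE ~ "neutral"
  )
  out
}

#' Drop small segments for reporting
#'
#' The conventional visualization/reporting filter: segments shorter than
#' `min_kb` kilobases are removed (the tiling property is intentionally
#' broken for display).
#'
#' @param segments tibble from [segment_logratio()].
#' @param min_kb minimum segment length in kb (default 25).
#' @return filtered tibble.
#' @export
filter_small_segments <- function(segments, min_kb = 25) {
  segments[segments$end - segments$start >= min_kb * 1000, , drop = FALSE]
}

#' Call a whole-chromosome copy-number event
#'
#' Emits an event when at least `min_fraction` of the chromosome length
#' shares a single non-neutral state.
#'
#' @param segments one chromosome's segments (one sample).
#' @param chrom_length chromosome length in bp.
#' @param min_fraction whole-chromosome coverage threshold (default 0.9).
#' @return one-row tibble (`chrom`, `kind`, `covered_fraction`) or a
#'   zero-row tibble when no whole-chromosome event is present.
#' @export
call_whole_chrom <- function(segments, chrom_length, min_fraction = 0.9) {
  empty <- tibble::tibble(chrom = character(), kind = character(),
                          covered_fraction = numeric())
  if (nrow(segments) == 0) return(empty)
  for (kind in c("loss", "gain")) {
    len <- sum((segments$end - segments$start)[segments$state == kind])
    frac <- len / chrom_length
    if (frac >= min_fraction) {
      return(tibble::tibble(chrom = segments$chrom[1], kind = kind,
                            covered_fraction = frac))
    }
  }
  empty
}

#' Detect chromothripsis-like oscillating copy-number patterns
#'
#' A chromosome is called positive when it carries at least `min_segments`
#' segments, at least `min_two_state` of the segments occupy just two copy
#' states, and at least `min_oscillation` of adjacent segment transitions
#' alternate between exactly those two states — the clustered two-state
#' oscillation characteristic of chromothripsis.
#'
#' @param segments one chromosome's segments (one sample).
#' @param min_segments minimum segment count (default 10).
#' @param min_oscillation minimum alternating-transition fraction (default 0.8).
#' @param min_two_state minimum fraction of segments in the two dominant
#'   states (default 0.9).
#' @return one-row tibble of class data (chrom, n_segments,
#'   n_state_switches, oscillation_fraction, two_state_fraction, positive).
#' @export
detect_chromothripsis <- function(segments, min_segments = 10,
                                  min_oscillation = 0.8, min_two_state = 0.9) {
  n <- nrow(segments)
  st <- segments$state
  switches <- if (n >= 2) sum(st[-1] != st[-n]) else 0L
  tab <- sort(table(st), decreasing = TRUE)
  top2 <- names(tab)[seq_len(min(2, length(tab)))]
  two_state_fraction <- if (n > 0) sum(st %in% top2) / n else 0
  osc <- if (n >= 2 && length(top2) == 2) {
    a <- st[-n]; b <- st[-1]
    mean(a != b & a %in% top2 & b %in% top2)
  } else 0
  tibble::tibble(
    chrom = if (n > 0) segments$chrom[1] else NA_character_,
    n_segments = n,
    n_state_switches = switches,
    oscillation_fraction = osc,
    two_state_fraction = two_state_fraction,
    positive = n >= min_segments && osc >= min_oscillation &&
      two_state_fraction >= min_two_state
  )
}
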