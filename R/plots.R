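#' Heatmap of pairwise shared SNV counts
#'
#' @param object a `shared_matrix` from [pairwise_shared()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.shared_matrix <- function(object, ...) {
  long <- tibble::as_tibble(object$counts, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "shared")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared SNVs") +
    ggplot2::theme_minimal()
}

#' 96-channel substitution profile barplot
#'
#' @param object a `profile96` from [count_96()].
#' @param ... unused.
#' @return a ggplot faceted by substitution class.
#' @exportS3Method
autoplot.profile96 <- function(object, ...) {
  ch <- sbs96_channels()
  df <- tibble::tibble(
    channel = factor(ch$channel, levels = ch$channel),
    sub = ch$sub,
    count = as.numeric(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$count,
                                   fill = .data$sub)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~sub, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none") +
    ggplot2::labs(x = NULL, y = "substitutions")
}

#' Signature loading barplot
#'
#' @param object a `signature_fit` from [fit_signatures()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.signature_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$active, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$signature, .data$loading)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "relative contribution") +
    ggplot2::theme_minimal()
}

#' Phasing scatter (reference vs test VAF per het SNP)
#'
#' @param object a `phase_call` from [phase_event()].
#' @param ... unused.
#' @return a ggplot mirroring the homolog-phasing scatter display.
#' @exportS3Method
autoplot.phase_call <- function(object, ...) {
  ggplot2::ggplot(object$snps,
                  ggplot2::aes(.data$vaf_reference, .data$vaf_test,
                               colour = .data$informative)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = paste0("VAF ", object$reference_sample),
      y = paste0("VAF ", object$test_sample),
      title = paste0("homolog call: ", object$homolog_call)
    ) +
    ggplot2::theme_minimal()
}

#' Copy-number profile plot for one sample
#'
#' @param segments segment tibble from [segment_logratio()] (optionally
#'   several chromosomes).
#' @return a ggplot of segment mean log2-ratios along the genome.
#' @export
plot_cna_profile <- function(segments) {
  ggplot2::ggplot(segments) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$log2_ratio, yend = .data$log2_ratio,
                   colour = .data$state),
      linewidth = 1.2
    ) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(loss = "dodgerblue3", neutral = "grey50", gain = "firebrick")
    ) +
    ggplot2::labs(x = "position", y = "log2 tumor/normal ratio") +
    ggplot2::theme_minimal()
}

#' Plot a maximum-parsimony tree with branch SNV counts and supports
#'
#' @param mp an `mp_tree` (after [assign_branch_counts()] /
#'   [bootstrap_support()] for counts and supports).
#' @param ... passed to [ape::plot.phylo()].
#' @return invisibly, the plotted phylo.
#' @export
plot_mp_tree <- function(mp, ...) {
  stopifnot(inherits(mp, "mp_tree"))
  ape::plot.phylo(mp$phy, show.node.label = TRUE, ...)
  invisible(mp$phy)
}
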