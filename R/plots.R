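#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_col
#'   geom_hline facet_grid labs theme_bw scale_fill_manual
NULL

#' @export
ggplot2::autoplot

genome_plot_base <- function(df) {
  df$chrom <- chrom_factor(df$chrom)
  df
}

#' Plot a normalized copy-number profile
#'
#' Probe-level normalized log2 ratios along the genome, faceted by
#' chromosome, optionally overlaid with segment means.
#'
#' @param object a `cgh_profile`.
#' @param segments optional `cgh_segments` to overlay.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cgh_profile <- function(object, segments = NULL, ...) {
  pr <- genome_plot_base(object$probes)
  p <- ggplot(pr, aes(x = .data$start / 1e6, y = .data$ratio)) +
    geom_point(size = 0.3, alpha = 0.4, colour = "grey30") +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (Mb)", y = "normalized log2 ratio") +
    theme_bw()
  if (!is.null(segments)) {
    sg <- genome_plot_base(tibble::as_tibble(segments))
    p <- p + geom_segment(
      data = sg,
      aes(x = .data$start / 1e6, xend = .data$end / 1e6,
          y = .data$seg_mean, yend = .data$seg_mean),
      colour = "red", linewidth = 0.8
    )
  }
  p
}

#' Plot a gain/loss call track
#'
#' Segments coloured by called state along the genome.
#'
#' @param object a `cgh_calls` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cgh_calls <- function(object, ...) {
  sg <- genome_plot_base(tibble::as_tibble(object))
  sg$call <- factor(c("loss", "neutral", "gain")[sg$state + 2],
                    levels = c("gain", "neutral", "loss"))
  ggplot(sg, aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                 y = .data$seg_mean, yend = .data$seg_mean,
                 colour = .data$call)) +
    geom_segment(linewidth = 1.2) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(gain = "firebrick", neutral = "grey60",
                 loss = "steelblue")) +
    labs(x = "position (Mb)", y = "segment mean") +
    theme_bw()
}

#' Bar chart of genome-imbalance summaries
#'
#' Percent genome gained and lost per sample, the standard side-by-side
#' imbalance display.
#'
#' @param summaries tibble of one-row outputs of [summarize_imbalance()],
#'   with a `sample_id` column.
#' @return A ggplot.
#' @export
plot_imbalance <- function(summaries) {
  long <- tidyr::pivot_longer(
    summaries[, c("sample_id", "pct_gained", "pct_lost")],
    -"sample_id", names_to = "direction", values_to = "pct")
  long$direction <- ifelse(long$direction == "pct_gained", "gained", "lost")
  ggplot(long, aes(x = .data$sample_id, y = .data$pct,
                   fill = .data$direction)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(gained = "firebrick", lost = "steelblue")) +
    labs(x = NULL, y = "percent genome changed") +
    theme_bw()
}

#' Stacked per-locus FISH copy-number distribution
#'
#' Proportion of cells in each copy-number category per locus, mirroring
#' the standard enumeration summary chart.
#'
#' @param fish_counts long tibble `locus`, `copy`, `n`.
#' @return A ggplot.
#' @export
plot_fish_counts <- function(fish_counts) {
  fc <- dplyr::mutate(fish_counts,
                      copy = factor(.data$copy, levels = fish_categories()))
  ggplot(fc, aes(x = .data$locus, y = .data$n, fill = .data$copy)) +
    geom_col(position = "fill") +
    labs(x = NULL, y = "fraction of cells", fill = "copies") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
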