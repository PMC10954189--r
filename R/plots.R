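#' Plot a LOD curve
#'
#' @param object A `lod_scan` from [scan_qtl()].
#' @param threshold Optional horizontal threshold line(s).
#' @param ... Unused.
#' @return A ggplot: LOD against cM, faceted by chromosome.
#' @export
autoplot.lod_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos_cm, y = .data$lod)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  subtitle = attr(object, "model")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot per-window male:female methylation ratios along a chromosome
#'
#' @param stats Per-window statistics from [window_sex_stats()].
#' @param blocks Optional block tibble from [find_blocks()]; drawn as shaded
#'   spans.
#' @param chrom Chromosome to show (default: first in `stats`).
#' @return A ggplot of `mf_ratio` against window start, log2 y-scale.
#' @export
plot_mf_ratio <- function(stats, blocks = NULL, chrom = stats$chrom[1]) {
  st <- stats[stats$chrom == chrom, ]
  p <- ggplot2::ggplot(st, ggplot2::aes(x = .data$start, y = .data$mf_ratio)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = paste0(chrom, " window start (bp)"),
                  y = "male:female methylation ratio") +
    ggplot2::theme_minimal()
  if (!is.null(blocks) && nrow(blocks)) {
    bl <- blocks[blocks$chrom == chrom, ]
    if (nrow(bl)) {
      p <- p + ggplot2::geom_rect(
        data = bl,
        ggplot2::aes(xmin = .data$start, xmax = .data$end),
        ymin = -Inf, ymax = Inf, alpha = 0.15,
        fill = "firebrick", inherit.aes = FALSE
      )
    }
  }
  p
}

#' Plot hotspot spans along the genome
#'
#' @param hotspots Tibble from [find_hotspots()] (or the bundled hotspot
#'   table).
#' @return A ggplot with one segment per hotspot spanning its shared
#'   confidence interval, sized by member count.
#' @export
plot_hotspots <- function(hotspots) {
  ggplot2::ggplot(hotspots,
                  ggplot2::aes(y = factor(.data$hotspot,
                                          levels = rev(hotspots$hotspot)))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lo_pos / 1e6,
                                       xend = .data$ci_hi_pos / 1e6,
                                       yend = factor(.data$hotspot),
                                       linewidth = .data$num_qtl),
                          colour = "steelblue4", lineend = "round") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, linewidth = "QTL") +
    ggplot2::theme_minimal()
}
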