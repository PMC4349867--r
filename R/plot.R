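#' Plot the ratio profile of one sector with its segmentation
#'
#' Scatter of the W- and Y-channel hybridization ratios along a chromosome
#' with the inferred genotype segments underlaid; the canonical readout plot
#' for spotting LOH transitions (heterozygous markers sit near ratio 1 in
#' both channels; homozygous regions separate the channels toward the 2-copy
#' and 0-copy means).
#'
#' @param ratios ratio tibble for one sector.
#' @param segments optional segment tibble from [segment_genome()].
#' @param chrom chromosome(s) to show (default: all present).
#' @return a ggplot object.
#' @export
plot_ratio_profile <- function(ratios, segments = NULL, chrom = NULL) {
  if (!is.null(chrom)) {
    ratios <- filter(ratios, .data$chrom %in% !!chrom)
    if (!is.null(segments)) segments <- filter(segments, .data$chrom %in% !!chrom)
  }
  long <- tidyr::pivot_longer(ratios, c("ratio_w", "ratio_y"),
                              names_to = "channel", values_to = "ratio")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos / 1e3, y = .data$ratio,
                                          colour = .data$channel)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(ratio_w = "#D55E00", ratio_y = "#0072B2"),
      labels = c(ratio_w = "W channel", ratio_y = "Y channel")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "hybridization ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    segs <- filter(segments, .data$state != "HET")
    if (nrow(segs)) {
      p <- p + ggplot2::geom_rect(
        data = segs,
        ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                     ymin = -Inf, ymax = Inf, fill = .data$state),
        inherit.aes = FALSE, alpha = 0.15)
    }
  }
  p
}

#' Plot classified LOH events along the genome
#'
#' Tract intervals per chromosome, coloured by event class; a compact
#' overview of where crossovers, conversions and BIR events fell.
#'
#' @param events classified event tibble.
#' @param genome genome tibble (for chromosome lengths).
#' @return a ggplot object.
#' @export
plot_events <- function(events, genome = loh_genome()) {
  ev <- filter(events, !is.na(.data$tract_start) | !is.na(.data$region_start))
  ev <- mutate(ev,
               lo = ifelse(is.na(.data$tract_start), .data$region_start,
                           .data$tract_start),
               hi = ifelse(is.na(.data$tract_end), .data$region_end,
                           .data$tract_end),
               chrom = factor(.data$chrom, levels = genome$chrom))
  ggplot2::ggplot(ev) +
    ggplot2::geom_segment(
      data = mutate(genome, chrom = factor(.data$chrom, levels = genome$chrom)),
      ggplot2::aes(x = 0, xend = .data$length / 1e6, y = .data$chrom,
                   yend = .data$chrom),
      linewidth = 0.4, colour = "grey70") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo / 1e6, xend = pmax(.data$hi, .data$lo + 2e4) / 1e6,
                   y = .data$chrom, yend = .data$chrom,
                   colour = .data$class),
      linewidth = 3) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "event class") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.loh_enrichment <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("observed", "expected"),
                            names_to = "kind", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "elements in breakpoint regions",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
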