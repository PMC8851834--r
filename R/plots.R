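#' Stacked class-composition bar for one or more partitions
#'
#' @param object a `partition_result` (or list of them via [plot_partitions()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.partition_result <- function(object, ...) {
  plot_partitions(list(object))
}

#' @rdname autoplot.partition_result
#' @param partitions list of `partition_result` objects.
#' @export
plot_partitions <- function(partitions) {
  df <- dplyr::bind_rows(lapply(partitions, function(p) {
    tibble::tibble(genome_id = p$genome_id, class = names(p$totals),
                   bp = unname(p$totals))
  }))
  df$class <- factor(df$class, levels = c("CONSERVED", "PLASTID_LIKE",
                                          "REPETITIVE", "SPECIFIC", "OTHER"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_id, y = .data$bp,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bp", fill = "sequence class") +
    ggplot2::theme_minimal()
}

#' Ribbon-style synteny plot of two genomes
#'
#' Draws the two genomes as horizontal bars and one ribbon per synteny
#' block; inverted blocks cross.
#'
#' @param blocks tibble from [chain_blocks()].
#' @param a_len,b_len genome lengths (bp).
#' @param a_name,b_name axis labels.
#' @return A ggplot object.
#' @export
plot_synteny <- function(blocks, a_len, b_len, a_name = "A", b_name = "B") {
  ribbons <- dplyr::bind_rows(lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    flip <- b$orientation == "inverted"
    tibble::tibble(
      block_id = b$block_id, orientation = b$orientation,
      x = c(b$a_start, b$a_end,
            if (flip) b$b_start else b$b_end,
            if (flip) b$b_end else b$b_start),
      y = c(1, 1, 0, 0))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = ribbons,
      ggplot2::aes(x = .data$x, y = .data$y,
                   group = .data$block_id, fill = .data$orientation),
      alpha = 0.5) +
    ggplot2::annotate("segment", x = 0, xend = a_len, y = 1.02, yend = 1.02,
                      linewidth = 3) +
    ggplot2::annotate("segment", x = 0, xend = b_len, y = -0.02, yend = -0.02,
                      linewidth = 3) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c(b_name, a_name)) +
    ggplot2::labs(x = "bp", y = NULL, fill = "orientation") +
    ggplot2::theme_minimal()
}

#' Coverage profile around located gene fragments
#'
#' @param coverage per-base depth vector.
#' @param fragments tibble from [locate_fragments()].
#' @param th [thresholds()] (drawn as the low/high coverage bands).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, fragments, th = thresholds()) {
  lo <- max(1L, min(fragments$t_start) - 500L)
  hi <- min(length(coverage), max(fragments$t_end) + 500L)
  df <- tibble::tibble(pos = lo:hi, depth = coverage[lo:hi])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_hline(yintercept = c(th$cov_low, th$cov_high),
                        linetype = "dashed", colour = c("blue", "red")) +
    ggplot2::geom_segment(
      data = fragments,
      ggplot2::aes(x = .data$t_start, xend = .data$t_end),
      y = -max(df$depth) * 0.04, yend = -max(df$depth) * 0.04,
      linewidth = 2, colour = "darkgreen") +
    ggplot2::geom_text(
      data = fragments,
      ggplot2::aes(x = (.data$t_start + .data$t_end) / 2, label = .data$label),
      y = -max(df$depth) * 0.1, size = 3) +
    ggplot2::labs(x = "target position (bp)", y = "read depth") +
    ggplot2::theme_minimal()
}
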