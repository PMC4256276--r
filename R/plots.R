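# ggplot2 views of the main result types.

#' Plot an insertion-site profile
#'
#' Stacked per-position base frequencies, annotated with the key positions
#' -6 and +5.
#'
#' @param object A [build_profile()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rigseq_profile <- function(object, ...) {
  d <- tidy(object)
  d$label <- factor(d$label, levels = colnames(object$matrix))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$freq, fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::geom_vline(xintercept = match(c("-6", "+5"), levels(d$label)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "position relative to insertion boundary",
                  y = "base frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot subsample unique-site counts
#'
#' @param object A [subsample_unique_counts()] object.
#' @param ... Unused.
#' @return A ggplot histogram of per-subset unique-site counts.
#' @export
autoplot.rigseq_subsample <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$unique_sites)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(
      x = sprintf("unique insertion sites per subset (S = %d)", object$S),
      y = "subsets"
    ) +
    ggplot2::theme_minimal()
}

#' Chromosome map of insertion events
#'
#' Vertical bars of relative retrotransposition frequency along the
#' chromosome, one panel per library.
#'
#' @param events Tibble from [relative_frequencies()].
#' @param replicon_role Which replicon role to draw (default chromosome).
#' @return A ggplot.
#' @export
plot_insertion_map <- function(events, replicon_role = "chromosome") {
  d <- as_tibble(events) |> filter(.data$role == replicon_role)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$boundary, y = .data$rel_freq)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$boundary, yend = 0),
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~library, ncol = 1) +
    ggplot2::labs(x = "chromosome position (nt)",
                  y = "relative retrotransposition frequency") +
    ggplot2::theme_minimal()
}

#' Replicon preference per library
#'
#' Stacked chromosome / donor-plasmid read fractions (over uniquely mapped
#' reads) per library.
#'
#' @param summary Tibble from [replicon_summary()].
#' @return A ggplot.
#' @export
plot_replicon_preference <- function(summary) {
  d <- as_tibble(summary) |>
    tidyr::pivot_longer(c("chromosome", "donor_plasmid"),
                        names_to = "replicon", values_to = "fraction")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$library, y = .data$fraction,
                                  fill = .data$replicon)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "uniquely mapped reads", fill = NULL) +
    ggplot2::theme_minimal()
}
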