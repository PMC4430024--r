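#' Plot a cross-species identity profile
#'
#' Smoothed identity along the alignment with called conserved regions
#' shaded and the identity cutoff drawn as a reference line.
#'
#' @param profile Numeric profile from [identity_profile()].
#' @param regions Optional conserved-region tibble from
#'   [call_conserved_regions()].
#' @param min_identity Cutoff line to draw (default 0.70).
#' @return A ggplot object.
#' @export
plot_identity_profile <- function(profile, regions = NULL,
                                  min_identity = 0.70) {
  df <- tibble(column = seq_along(profile) - 1L, identity = profile)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$identity))
  if (!is.null(regions) && nrow(regions)) {
    gg <- gg + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25
    )
  }
  gg +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = min_identity, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "alignment column", y = "windowed identity") +
    ggplot2::theme_minimal()
}

#' Plot motif hits as tracks along sequences
#'
#' One horizontal lane per transcription factor, faceted by sequence;
#' segment shading encodes the relative score.
#'
#' @param hits A hit tibble.
#' @param seq_lengths Optional named vector of sequence lengths to fix the
#'   x ranges.
#' @return A ggplot object.
#' @export
plot_hit_tracks <- function(hits, seq_lengths = NULL) {
  stopifnot(is.data.frame(hits))
  gg <- ggplot2::ggplot(
    hits,
    ggplot2::aes(x = .data$start, xend = .data$end,
                 y = .data$tf, yend = .data$tf,
                 colour = .data$rel_score)
  ) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_wrap(~seq_id, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "rel score") +
    ggplot2::theme_minimal()
  if (!is.null(seq_lengths)) {
    gg <- gg + ggplot2::xlim(0, max(seq_lengths))
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of PWM weights
#'
#' @param object A `crossreg_pwm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossreg_pwm <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(.data$position, .data$base, fill = .data$weight)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = paste0(object$tf_name, " log-odds weights"),
                  x = "motif position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dataset-vs-random background comparison plot
#'
#' Paired bars of mean hit counts on the dataset and on the random
#' background for each factor.
#'
#' @param comparison Tibble from [specificity_comparison()] (rows may be
#'   bound over factors).
#' @return A ggplot object.
#' @export
plot_background_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(
    comparison, c("mean_data", "mean_rand"),
    names_to = "set", values_to = "mean_hits"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$tf, .data$mean_hits, fill = .data$set)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean hits per sequence", fill = NULL) +
    ggplot2::theme_minimal()
}
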