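#' Plot per-residue vote scores along a query sequence
#'
#' Lollipop-style profile of the vote score with called interface residues
#' highlighted; positions without votes are shown as open marks at zero.
#'
#' @param object A `ppi_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_prediction <- function(object, ...) {
  d <- tidy(object)
  d$status <- dplyr::case_when(
    d$n_votes == 0 ~ "no vote",
    d$call == 1 ~ "interface",
    TRUE ~ "non-interface"
  )
  d$shown_score <- dplyr::coalesce(d$vote_score, 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$shown_score)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status, shape = .data$status)) +
    ggplot2::scale_colour_manual(values = c(
      "interface" = "#c0392b", "non-interface" = "#2c3e50", "no vote" = "grey60"
    )) +
    ggplot2::scale_shape_manual(values = c(
      "interface" = 16, "non-interface" = 16, "no vote" = 1
    )) +
    ggplot2::labs(
      x = "position", y = "vote score",
      title = sprintf("%s (%s zone, %d templates)", object$query_id,
                      object$zone %||% "no", length(object$templates))
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ppi_prediction
#' @export
plot.ppi_prediction <- function(x, ...) print(autoplot.ppi_prediction(x, ...))

#' Plot a precision-recall sweep
#'
#' @param sweep Tibble from [pr_sweep()].
#' @return A ggplot object.
#' @export
plot_pr_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$sensitivity, y = .data$specificity)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$threshold), size = 2) +
    ggplot2::scale_colour_viridis_c(name = "threshold") +
    ggplot2::labs(x = "sensitivity (recall)", y = "specificity (precision)") +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot predicted interface conservation against zone thresholds
#'
#' Scatter of hits in the (log expectation value, positive score) plane,
#' coloured by assigned homology zone — a quick view of why templates were
#' or were not used.
#'
#' @param hits Tibble with `log_eval`, `positive_score` and a `zone`
#'   column (see [classify_zone_nps()]).
#' @return A ggplot object.
#' @export
plot_zone_map <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$log_eval, y = .data$positive_score,
                                     colour = .data$zone)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "log(EVal)", y = "positive score (%)", colour = "zone") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
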