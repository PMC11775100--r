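#' Plot a person's eGFR trajectory
#'
#' Date versus eGFR for one or more persons, with the CKD band (eGFR < 60)
#' shaded, points coloured by source, and vertical dotted lines at
#' kidney-relevant diagnostic events.
#'
#' @param assessments Assessment tibble.
#' @param persons Character vector of person ids to show.
#' @param events Optional diagnostic-event tibble.
#' @param ckd_threshold eGFR below which the band is shaded (default 60).
#' @return A ggplot object (facetted when several persons are given).
#' @export
plot_trajectory <- function(assessments, persons, events = NULL,
                            ckd_threshold = 60) {
  df <- dplyr::filter(assessments, .data$person_id %in% persons)
  if (nrow(df) == 0) abort("No assessments for the requested persons.")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$exam_date, y = .data$egfr)) +
    ggplot2::annotate("rect", xmin = structure(-Inf, class = "Date"),
                      xmax = structure(Inf, class = "Date"),
                      ymin = -Inf, ymax = ckd_threshold,
                      alpha = 0.12, fill = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$source), size = 1.8) +
    ggplot2::scale_colour_manual(values = c(SC = "black", eMR = "firebrick")) +
    ggplot2::labs(x = "Date of exam", y = "eGFR (mL/min/1.73m²)",
                  colour = "Source")
  if (!is.null(events)) {
    ev <- dplyr::filter(events, .data$person_id %in% persons)
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_vline(
        data = ev,
        ggplot2::aes(xintercept = .data$event_date,
                     linetype = .data$category),
        linewidth = 0.4, colour = "darkgreen"
      ) + ggplot2::labs(linetype = "Event")
    }
  }
  if (length(persons) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$person_id),
                                 scales = "free_x")
  }
  p
}

#' @describeIn build_bias_table Plot the bias table: calendar year versus
#'   correction factor, coloured by provenance, with the no-bias line at 1.
#' @param object A `bias_table`.
#' @param ... Unused.
#' @export
autoplot.bias_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$factor)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$provenance), size = 2) +
    ggplot2::labs(x = "Calendar year", y = "Correction factor GM(SC)/GM(eMR)",
                  colour = "Provenance")
}

#' @describeIn decline_regression Coefficient plot with 95% intervals.
#' @param object A `decline_reg`.
#' @export
autoplot.decline_reg <- function(object, ...) {
  td <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Effect on annual eGFR decline (mL/min/1.73m²/yr)",
                  y = NULL)
}
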