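# ggplot2 views of the tabular result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an interaction table
#'
#' Distance distribution of the enumerated contacts, coloured by kind.
#'
#' @param object a `tc_interactions` tibble from [enumerate_interactions()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tc_interactions
#' @export
autoplot.tc_interactions <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance, fill = .data$kind)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0,
                            position = "stack") +
    ggplot2::labs(x = "contact distance (Å)", y = "contacts",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a refinement report
#'
#' Start and end energies of each refinement stage.
#'
#' @param object a `refinement_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot refinement_report
#' @export
autoplot.refinement_report <- function(object, ...) {
  se <- object$stage_energies
  se$stage <- factor(se$stage, levels = unique(se$stage))
  long <- tidyr::pivot_longer(se, c("e_start", "e_end"),
                              names_to = "point", values_to = "energy")
  long$point <- factor(long$point, levels = c("e_start", "e_end"),
                       labels = c("start", "end"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$energy,
                                     group = .data$point,
                                     colour = .data$point)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$stage), colour = "grey50") +
    ggplot2::labs(x = NULL, y = "energy (kcal/mol)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare degrader scores across a series
#'
#' Bar chart of total scores (more negative = more stable predicted
#' complex), optionally coloured by a degradation label.
#'
#' @param scores named list of `degrader_score` objects.
#' @param labels optional character vector (e.g. `"strong"`/`"poor"`)
#'   parallel to `scores`.
#' @return a ggplot object.
#' @export
plot_score_comparison <- function(scores, labels = NULL) {
  df <- dplyr::bind_rows(lapply(scores, glance), .id = "degrader")
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$degrader,
                                                           .data$total),
                                        y = .data$total))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$label))
  }
  p + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "degrader TC score (kcal/mol)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
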