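#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PFAS comparison matrix
#'
#' Tile plot of verdicts, records by definitions — the visual counterpart of
#' the cross-definition set comparison.
#'
#' @param object A `pfas_matrix` from [classify_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfas_matrix <- function(object, ...) {
  long <- tidy(object)
  long$record_id <- factor(long$record_id, levels = rev(object$matrix$record_id))
  long$definition_id <- factor(long$definition_id,
                               levels = names(object$totals))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$definition_id,
                                     y = .data$record_id,
                                     fill = .data$is_pfas)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey95"),
                               name = "PFAS") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Fluorine-fraction distribution of a classified library
#'
#' Histogram of the fluorine atom-count fraction (hydrogen excluded) across
#' records, with the 30% combined-definition threshold marked — useful for
#' seeing how much of a library the formula clause alone captures.
#'
#' @param classified A [pfas_classify()] result.
#' @param threshold Reference threshold to mark (default 0.30).
#' @return A ggplot object.
#' @export
plot_fluorine_distribution <- function(classified, threshold = 0.30) {
  per_record <- classified |>
    dplyr::distinct(.data$record_id, .data$atom_fraction_excl_h)
  ggplot2::ggplot(per_record,
                  ggplot2::aes(x = .data$atom_fraction_excl_h)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "#67a9cf", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = "fluorine atom fraction (excluding H)",
                  y = "records") +
    ggplot2::theme_minimal()
}
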