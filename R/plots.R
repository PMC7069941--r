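#' Plot the tag length distribution per library
#'
#' @param len_dist Output of [length_distribution()].
#' @param weight `"total"` (read-weighted) or `"unique"`.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(len_dist, weight = c("total", "unique")) {
  weight <- match.arg(weight)
  ggplot2::ggplot(len_dist,
                  ggplot2::aes(x = .data$length, y = .data[[weight]],
                               fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = 18:30) +
    ggplot2::labs(x = "tag length (nt)", y = paste(weight, "tags"),
                  fill = "library") +
    ggplot2::theme_minimal()
}

#' Plot first-base composition by length class
#'
#' @param composition Output of [base_composition()] or
#'   [first_base_profile()].
#' @return A ggplot (stacked bars of A/C/G/U frequencies at position 1).
#' @export
plot_first_base <- function(composition) {
  d <- composition
  if ("position" %in% names(d)) d <- dplyr::filter(d, .data$position == 1L)
  ggplot2::ggplot(dplyr::filter(d, !.data$insufficient_data),
                  ggplot2::aes(x = factor(.data$length), y = .data$freq,
                               fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "length (nt)", y = "first-base frequency",
                  fill = "base") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of differential-expression results
#'
#' Infinite fold changes (stage-specific ids) are drawn at the panel edges.
#'
#' @param de A `srna_de` tibble from [call_de()].
#' @param pair Optional single pair label to show.
#' @return A ggplot.
#' @export
plot_de <- function(de, pair = NULL) {
  d <- as_tibble(de)
  if (!is.null(pair)) d <- dplyr::filter(d, .data$pair == !!pair)
  finite <- d$log2fc[is.finite(d$log2fc)]
  edge <- if (length(finite)) max(abs(finite)) + 1 else 10
  d$lfc_plot <- pmax(pmin(d$log2fc, edge), -edge)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lfc_plot,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "log2 fold change (B/A)", y = "-log10 p",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Bar plot of stage-presence pattern tallies
#'
#' @param patterns A `srna_patterns` tibble from [classify_patterns()].
#' @return A ggplot.
#' @export
plot_patterns <- function(patterns) {
  d <- dplyr::filter(as_tibble(patterns), !is.na(.data$label)) |>
    count(.data$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "pattern", y = "miRNAs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
#' @method autoplot srna_de
#' @param object,... Passed to [plot_de()].
#' @rdname plot_de
autoplot.srna_de <- function(object, ...) plot_de(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
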