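#' Cluster plot of called wells
#'
#' The classic KASP cluster plot: background-subtracted FAM signal
#' against HEX signal, one panel per marker, wells coloured by call
#' state. Called wells form up to three arms (homozygous X near the FAM
#' axis, heterozygotes in between, homozygous Y near the HEX axis);
#' no-calls and no-template controls sit near the origin or between
#' arms.
#'
#' @param object a `kasp_calls` tibble (signals are reconstructed from
#'   the stored polar representation).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kasp_calls <- function(object, ...) {
  df <- object |>
    dplyr::mutate(
      fam = .data$magnitude * cospi(dplyr::coalesce(.data$theta, 45) / 180),
      hex = .data$magnitude * sinpi(dplyr::coalesce(.data$theta, 45) / 180),
      state = factor(.data$state, levels = c("XX", "XY", "YY", "no_call"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fam, y = .data$hex,
                                   colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$marker)) +
    ggplot2::scale_colour_manual(
      values = c(XX = "#1f77b4", XY = "#2ca02c", YY = "#d62728",
                 no_call = "grey60"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "FAM (allele X)", y = "HEX (allele Y)",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kasp_calls
#' @export
plot_cluster <- function(object, ...) autoplot.kasp_calls(object, ...)

#' Heatmap of a confusion matrix
#'
#' @param object a `kasp_confusion`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kasp_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(object$table), stringsAsFactors = FALSE)
  names(df) <- c("reference", "assigned", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assigned, y = .data$reference,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey90", high = "#2c3e70") +
    ggplot2::labs(x = "assigned", y = "reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
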