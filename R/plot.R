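#' Plot predicted stability changes
#'
#' Bar chart of the predicted stability change per variant, coloured by
#' effect class; when both modes were run, sequence- and structure-based
#' predictions are shown side by side.
#'
#' @param object A `ddg_prediction` tibble from [predict_ddg()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddg_prediction
#' @export
autoplot.ddg_prediction <- function(object, ...) {
  long <- object |>
    dplyr::select("variant", dplyr::starts_with("ddg_")) |>
    tidyr::pivot_longer(dplyr::starts_with("ddg_"),
                        names_to = "mode", values_to = "ddg",
                        names_prefix = "ddg_") |>
    dplyr::mutate(mode = toupper(.data$mode),
                  effect = classify_effect(.data$ddg))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$ddg,
                                     fill = .data$effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::scale_fill_manual(values = c(increase = "#2166ac",
                                          decrease = "#b2182b",
                                          neutral = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(Delta * Delta * G ~ "(kcal/mol)"),
                  fill = "effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a sequence profile as a frequency heatmap
#'
#' @param profile A `ddg_profile`.
#' @param positions Optional integer vector restricting the plotted
#'   positions.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, positions = NULL) {
  stopifnot(inherits(profile, "ddg_profile"))
  df <- as_tibble.ddg_profile(profile) |>
    tidyr::pivot_longer(dplyr::all_of(AA_STANDARD),
                        names_to = "aa", values_to = "freq")
  if (!is.null(positions)) df <- dplyr::filter(df, .data$position %in% positions)
  df$aa <- factor(df$aa, levels = rev(AA_STANDARD))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$aa,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "query position", y = NULL, fill = "frequency") +
    ggplot2::theme_minimal()
}
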