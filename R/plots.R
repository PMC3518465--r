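#' Plot a binned SRT distribution
#'
#' Correct (thick) and error (thin) response percentages per 10-ms bin,
#' with the minimal SRT marked when supplied.
#'
#' @param dist an [bin_srt_distribution()] result.
#' @param onset_ms optional onset (ms) to mark.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_srt_distribution <- function(dist, onset_ms = NULL, title = NULL) {
  stopifnot(inherits(dist, "srt_distribution"))
  df <- dist$bins |>
    tidyr_pivot() |>
    dplyr::mutate(pct = 100 * .data$count / dist$n_total)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lower + dist$bin_width_ms / 2,
                                        y = .data$pct,
                                        linewidth = .data$kind)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$kind)) +
    ggplot2::scale_linewidth_manual(values = c(correct = 1.1, error = 0.4),
                                    name = NULL) +
    ggplot2::labs(x = "SRT (ms)", y = "% of responses", title = title) +
    ggplot2::coord_cartesian(xlim = c(80, 450)) +
    ggplot2::theme_minimal()
  if (!is.null(onset_ms) && !is.na(onset_ms))
    p <- p + ggplot2::geom_vline(xintercept = onset_ms, linetype = 2)
  p
}

# long format without depending on tidyr
tidyr_pivot <- function(bins) {
  dplyr::bind_rows(
    tibble::tibble(bin_lower = bins$bin_lower, kind = "correct",
                   count = bins$n_correct),
    tibble::tibble(bin_lower = bins$bin_lower, kind = "error",
                   count = bins$n_error))
}

#' Scatter of model accuracies: object task vs scene task
#'
#' One point per feature model, with the chance line; optional human points
#' (e.g. behavioural accuracies) overlaid.
#'
#' @param ranked tibble from [rank_models()].
#' @param human optional tibble with `label`, `object`, `scene` (percent).
#' @return a ggplot object.
#' @export
plot_model_comparison <- function(ranked, human = NULL) {
  wide <- dplyr::inner_join(
    dplyr::filter(ranked, .data$task == "object") |>
      dplyr::select("model", object = "mean_accuracy"),
    dplyr::filter(ranked, .data$task == "scene") |>
      dplyr::select("model", scene = "mean_accuracy"),
    by = "model")
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$object, y = .data$scene)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$model), vjust = -1) +
    ggplot2::coord_cartesian(xlim = c(40, 100), ylim = c(40, 100)) +
    ggplot2::labs(x = "object task accuracy (%)",
                  y = "scene task accuracy (%)") +
    ggplot2::theme_minimal()
  if (!is.null(human))
    p <- p + ggplot2::geom_point(data = human,
                                 ggplot2::aes(x = .data$object,
                                              y = .data$scene),
                                 shape = 17, size = 3, colour = "red") +
      ggplot2::geom_text(data = human,
                         ggplot2::aes(x = .data$object, y = .data$scene,
                                      label = .data$label),
                         vjust = -1, colour = "red")
  p
}
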