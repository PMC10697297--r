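#' Plot the recorded training loss of a forecaster
#'
#' @param model A trained `glp_model`.
#' @return A ggplot: per-epoch mean training loss, one panel per stage.
#' @export
plot_loss <- function(model) {
  stopifnot(inherits(model, "glp_model"), length(model$loss) > 0L)
  df <- dplyr::bind_rows(purrr::imap(model$loss, function(tr, i) {
    tibble::tibble(
      stage = paste0(i, ": ", tr$stage),
      epoch = seq_along(tr$loss), loss = tr$loss
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(
      x = "epoch", y = "mean training MSE",
      title = paste("Training loss:", model$marker)
    )
}

#' Compare forecasting performance across training regimes
#'
#' @param results A per-fold results tibble with columns `regime` and
#'   `r2` (e.g. `ablation_grid()$results` or stacked [cross_validate()]
#'   outputs).
#' @return A ggplot: R-squared distribution per regime.
#' @export
plot_regime_comparison <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$regime, y = .data$r2)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 17, size = 3) +
    ggplot2::labs(x = "training regime", y = expression(R^2))
}

#' Plot progress-output distributions before and after rollout
#'
#' Shows, per event class, the denormalized forecaster output of one
#' marker at the three snapshot horizons — the visual counterpart of the
#' converge-vs-scatter behaviour of stable versus diverging patients.
#'
#' @param snapshot Output of [snapshot_export()].
#' @param marker Marker column to plot.
#' @return A ggplot.
#' @export
plot_snapshot <- function(snapshot, marker) {
  stopifnot(marker %in% names(snapshot))
  ggplot2::ggplot(
    snapshot,
    ggplot2::aes(
      x = .data$horizon, y = .data[[marker]],
      colour = .data$event_label
    )
  ) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.6) +
    ggplot2::labs(
      x = "rollout horizon", y = paste(marker, "(raw scale)"),
      colour = "event"
    )
}

#' @rdname plot_regime_comparison
#' @param object A `glp_eval` tibble.
#' @param ... Unused.
#' @export
autoplot.glp_eval <- function(object, ...) {
  plot_regime_comparison(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
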