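#' Plot a single-oscillator trajectory
#'
#' Real parts of the oscillator state and of the input against time.
#'
#' @param object A `sappa_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sappa_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "time_s", "re_z", "re_F"),
    cols = c("re_z", "re_F"), names_to = "signal", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "Re", colour = NULL)
}

#' Plot solo-tapping asynchrony against stimulus period
#'
#' @param object A `sappa_exp1` result from [run_experiment1()].
#' @param ... Unused.
#' @return A ggplot object: mean asynchrony (ms) versus IOI (ms), coloured
#'   by profile, line type by feedback condition.
#' @export
autoplot.sappa_exp1 <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ioi_ms, y = .data$mean_asynchrony_ms,
                               colour = .data$profile,
                               linetype = .data$feedback)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus period (ms)", y = "mean asynchrony (ms)")
}

#' Plot a (D, tau) asynchrony sweep as a heat map
#'
#' Failed (unsynchronized) cells are drawn black.
#'
#' @param object A `sappa_sweep` from [sweep_asynchrony()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sappa_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_s, y = .data$D,
                                       fill = .data$asynchrony_ms)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = "D",
                  fill = "asynchrony (ms)")
}

#' Plot lead/lag fraction against transmission latency
#'
#' @param object A `sappa_exp3` from [run_experiment3()].
#' @param ... Unused.
#' @return A ggplot object with the per-latency mean beat fraction and its
#'   least-squares line.
#' @export
autoplot.sappa_exp3 <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$tl_ms, y = .data$mean_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "transmission latency (ms)",
                  y = "mean fraction of a 90 bpm beat")
}
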