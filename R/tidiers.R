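#' Tidy the per-cycle asynchrony series
#'
#' @param x An `asynchrony_series`.
#' @param ... Unused.
#' @return A tibble with one row per stimulus cycle: `cycle`,
#'   `stim_time_s`, `model_peak_s`, `diff_s`, `diff_ms`, `steady` (is the
#'   cycle part of the steady-state window).
#' @export
tidy.asynchrony_series <- function(x, ...) {
  pc <- x$per_cycle
  steady <- if (is.na(x$steady_onset_index)) rep(FALSE, nrow(pc)) else
    seq_len(nrow(pc)) >= x$steady_onset_index
  tibble(cycle = seq_len(nrow(pc)), stim_time_s = pc$stim_time_s,
         model_peak_s = pc$model_peak_s, diff_s = pc$diff_s,
         diff_ms = pc$diff_s * 1000, steady = steady)
}

#' One-row summary of an asynchrony series
#'
#' @inheritParams tidy.asynchrony_series
#' @return A one-row tibble: `mean_asynchrony_ms`, `sd_ms`, `synchronized`,
#'   `steady_onset_index`, `n_cycles`, `fs_hz`.
#' @export
glance.asynchrony_series <- function(x, ...) {
  tibble(mean_asynchrony_ms = x$mean_ms, sd_ms = x$sd_ms,
         synchronized = x$synchronized,
         steady_onset_index = x$steady_onset_index,
         n_cycles = nrow(x$per_cycle), fs_hz = x$fs)
}

#' Tidy the per-turn lead/lag table
#'
#' @param x A `leadlag_result`.
#' @param ... Unused.
#' @return A tibble with columns `turn`, `active`, `L_s`, `L_ms`,
#'   `fraction`, `percent`.
#' @export
tidy.leadlag_result <- function(x, ...) x$per_turn

#' One-row summary of a lead/lag result
#'
#' @inheritParams tidy.leadlag_result
#' @return A one-row tibble: `tl_ms`, `mean_fraction`, `n_turns`.
#' @export
glance.leadlag_result <- function(x, ...) {
  tibble(tl_ms = x$tl_ms, mean_fraction = x$mean_fraction,
         n_turns = nrow(x$per_turn))
}

#' Tidy the per-latency summary of a turn-taking experiment
#'
#' @param x A `sappa_exp3`.
#' @param ... Unused.
#' @return The per-latency summary tibble (`tl_ms`, `mean_fraction`,
#'   `n_turns`).
#' @export
tidy.sappa_exp3 <- function(x, ...) x$summary

#' One-row summary of a turn-taking experiment
#'
#' @inheritParams tidy.sappa_exp3
#' @return A one-row tibble with the latency slope and configuration.
#' @export
glance.sappa_exp3 <- function(x, ...) {
  tibble(profile = x$config$profile, delta_hz = x$config$delta_hz,
         slope_per_ms = x$slope_per_ms, n_latencies = nrow(x$summary))
}

#' Tidy the parameter-fit objective grid
#'
#' @param x A `sappa_fit`.
#' @param ... Unused.
#' @return A tibble with one row per grid point: `D`, `tau`, `A`,
#'   `objective`.
#' @export
tidy.sappa_fit <- function(x, ...) as_tibble(x$grid)

#' One-row summary of a parameter fit
#'
#' @inheritParams tidy.sappa_fit
#' @return A one-row tibble: `best_D`, `best_tau`, `best_A`, `objective`.
#' @export
glance.sappa_fit <- function(x, ...) {
  tibble(best_D = x$best_D, best_tau = x$best_tau, best_A = x$best_A,
         objective = x$objective)
}
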