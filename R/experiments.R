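#' Solo metronome synchronization across stimulus periods
#'
#' Drives a single oscillator with a periodic stimulus at each inter-onset
#' interval (IOI) and reports the steady-state mean asynchrony. With
#' `feedback = "on"` the oscillator also receives its own instantaneous
#' activity (`A z`, normalised combination); with `"off"` it is driven by
#' the bare carrier. The oscillator's natural frequency always matches the
#' stimulus frequency (`f = fs = 1000 / IOI`).
#'
#' Runs that never reach a steady state are kept as rows flagged
#' `synchronized = FALSE` (with a warning), never dropped silently.
#'
#' @param profiles Character vector of profiles to run
#'   (`"musician"`, `"nonmusician"`).
#' @param feedback Character vector of feedback conditions (`"on"`, `"off"`).
#' @param ioi_ms Stimulus periods in ms (default 1000 to 3500 in steps of
#'   250).
#' @param kind Carrier kind: `"sinusoid"` (default) or `"square_wave"`.
#' @param cycles Number of stimulus cycles to simulate per IOI (default 20).
#' @param dt Integration step in seconds.
#' @return A `sappa_exp1` tibble with columns `profile`, `feedback`,
#'   `ioi_ms`, `mean_asynchrony_ms`, `sd_ms`, `synchronized`.
#' @examples
#' \donttest{
#' run_experiment1(profiles = "musician", feedback = "on",
#'                 ioi_ms = c(1000, 2000))
#' }
#' @export
run_experiment1 <- function(profiles = c("musician", "nonmusician"),
                            feedback = c("on", "off"),
                            ioi_ms = seq(1000, 3500, by = 250),
                            kind = c("sinusoid", "square_wave"),
                            cycles = 20, dt = 1e-3) {
  kind <- match.arg(kind)
  grid <- tidyr::expand_grid(profile = profiles, feedback = feedback,
                             ioi_ms = ioi_ms)
  rows <- purrr::pmap(grid, function(profile, feedback, ioi_ms) {
    f <- 1000 / ioi_ms
    params <- sappa_params(profile, f = f)
    spec <- stimulus_spec(kind, fs = f,
                          feedback_mode = if (feedback == "on") "constant_self" else "off")
    traj <- sappa_integrate(params, spec, duration = cycles * ioi_ms / 1000,
                            dt = dt)
    g <- glance(measure_asynchrony(traj))
    tibble(profile = profile, feedback = feedback, ioi_ms = ioi_ms,
           mean_asynchrony_ms = g$mean_asynchrony_ms, sd_ms = g$sd_ms,
           synchronized = g$synchronized)
  })
  out <- bind_rows(rows)
  if (any(!out$synchronized)) {
    rlang::warn(sprintf("%d run(s) did not synchronize; see the `synchronized` column.",
                        sum(!out$synchronized)))
  }
  attr(out, "config") <- list(profiles = profiles, feedback = feedback,
                              ioi_ms = ioi_ms, kind = kind, cycles = cycles,
                              dt = dt)
  class(out) <- c("sappa_exp1", class(out))
  out
}

#' Solo alternating-beat tapping (half-cycle auditory feedback)
#'
#' One oscillator synchronizes with a 1 Hz sinusoid. With
#' `feedback = "on"` its own instantaneous activity is added to the input
#' during the second half of every stimulus cycle only (the half-cycle in
#' which the tap and its auditory feedback occur); with `"off"` the carrier
#' is the sole input throughout.
#'
#' @param profile `"musician"` or `"nonmusician"`.
#' @param feedback `"on"` or `"off"`.
#' @param duration_s Simulated time in seconds (default 20).
#' @param dt Integration step in seconds.
#' @return An `asynchrony_series`; the full trajectory is attached as the
#'   `trajectory` attribute.
#' @export
run_experiment2_solo <- function(profile = "musician", feedback = c("on", "off"),
                                 duration_s = 20, dt = 1e-3) {
  feedback <- match.arg(feedback)
  params <- sappa_params(profile, f = 1)
  spec <- stimulus_spec("sinusoid", fs = 1,
                        feedback_mode = if (feedback == "on") "half_cycle_self" else "off")
  traj <- sappa_integrate(params, spec, duration = duration_s, dt = dt)
  res <- measure_asynchrony(traj)
  attr(res, "trajectory") <- traj
  res
}

#' Duet alternating tapping with a shared metronome
#'
#' Two oscillators share a 1 Hz sinusoidal stimulus: oscillator 1 receives
#' the carrier with a positive sign (in-phase role) and oscillator 2 the
#' negated carrier (anti-phase role). With `feedback = "on"` each also
#' receives `A z(k)`, where `k` toggles between self and partner every half
#' stimulus cycle; with `"off"` both receive only their carrier. The
#' in-phase oscillator is measured against stimulus peaks, the anti-phase
#' oscillator against stimulus valleys.
#'
#' @inheritParams run_experiment2_solo
#' @param normalize Normalise the combined input (default `TRUE`).
#' @return A list with `model1` and `model2` `asynchrony_series`; the duet
#'   trajectory is attached as the `trajectory` attribute.
#' @export
run_experiment2_duet <- function(profile = "musician", feedback = c("on", "off"),
                                 duration_s = 20, dt = 1e-3, normalize = TRUE) {
  feedback <- match.arg(feedback)
  params <- sappa_params(profile, f = 1)
  traj <- sappa_integrate_duet(params, params, fs = 1, feedback = feedback,
                               normalize = normalize, duration = duration_s,
                               dt = dt)
  res <- list(
    model1 = measure_asynchrony(traj, oscillator = 1L, event = "peak"),
    model2 = measure_asynchrony(traj, oscillator = 2L, event = "valley")
  )
  attr(res, "trajectory") <- traj
  res
}

#' Turn-taking duet under transmission latencies
#'
#' Two oscillators (no external sinusoid, natural frequency 1.5 Hz by
#' default, i.e. 90 bpm) alternate turns: the active oscillator receives its
#' own activity scaled by `A` while the passive one receives the active
#' oscillator's state delayed by the transmission latency. For each latency
#' the per-turn lead/lag statistic `L` is computed (see [lead_lag()]) and
#' the mean beat fraction per latency is summarised, together with the
#' least-squares slope of the fraction against the latency.
#'
#' @param profile `"musician"` or `"nonmusician"`.
#' @param tl_ms Transmission latencies in ms (default 0 to 78 ms).
#' @param delta_hz Frequency detuning offset in Hz applied to both
#'   oscillators; a positive value makes them run slightly fast and shifts
#'   the lead/lag curve upward.
#' @param f_hz Natural frequency in Hz (default 1.5).
#' @param duration_s Trial length in seconds (default 30).
#' @param warmup_turns Number of initial turns excluded from the per-turn
#'   statistics (default 3; covers the initiator's solo cycle and the
#'   first handovers).
#' @param dt Integration step in seconds.
#' @param literal_joiner_sign Passed to [sappa_integrate_turns()].
#' @return A `sappa_exp3` object: `summary` tibble (`tl_ms`,
#'   `mean_fraction`, `n_turns`), `per_turn` tibble across latencies,
#'   `slope_per_ms` (least-squares slope of the mean fraction vs latency),
#'   and the configuration echo.
#' @examples
#' \donttest{
#' ex3 <- run_experiment3(tl_ms = c(0, 39, 78), duration_s = 20)
#' glance(ex3)
#' }
#' @export
run_experiment3 <- function(profile = "musician",
                            tl_ms = c(0, 10, 20, 39, 58, 78),
                            delta_hz = 0, f_hz = 1.5, duration_s = 30,
                            warmup_turns = 3L, dt = 1e-3,
                            literal_joiner_sign = FALSE) {
  params <- sappa_params(profile, f = f_hz, delta = delta_hz)
  per_tl <- purrr::map(tl_ms, function(tl) {
    traj <- sappa_integrate_turns(params, params, tl = tl / 1000,
                                  duration = duration_s, dt = dt,
                                  literal_joiner_sign = literal_joiner_sign)
    turns <- turn_schedule(traj)
    claps1 <- cycle_completions(traj$re_z1, traj$im_z1, traj$time_s)
    claps2 <- cycle_completions(traj$re_z2, traj$im_z2, traj$time_s)
    ll <- lead_lag(claps1, claps2, turns, tl_ms = tl)
    ll$per_turn <- dplyr::filter(ll$per_turn, .data$turn > warmup_turns + 1L)
    ll$mean_fraction <- mean(ll$per_turn$fraction)
    ll
  })
  per_turn <- bind_rows(lapply(per_tl, function(ll) {
    mutate(ll$per_turn, tl_ms = ll$tl_ms)
  }))
  summary <- tibble(
    tl_ms = tl_ms,
    mean_fraction = vapply(per_tl, function(ll) ll$mean_fraction, numeric(1)),
    n_turns = vapply(per_tl, function(ll) nrow(ll$per_turn), integer(1))
  )
  slope <- unname(coef(lm(mean_fraction ~ tl_ms, data = summary))[2])
  structure(
    list(summary = summary, per_turn = per_turn, slope_per_ms = slope,
         config = list(profile = profile, tl_ms = tl_ms, delta_hz = delta_hz,
                       f_hz = f_hz, duration_s = duration_s,
                       warmup_turns = warmup_turns, dt = dt,
                       literal_joiner_sign = literal_joiner_sign)),
    class = "sappa_exp3"
  )
}

#' @export
print.sappa_exp3 <- function(x, ...) {
  cat(sprintf("<sappa_exp3> profile = %s, delta = %g Hz, slope = %.5f / ms\n",
              x$config$profile, x$config$delta_hz, x$slope_per_ms))
  print(x$summary)
  invisible(x)
}
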