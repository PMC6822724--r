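#' Delay history buffer
#'
#' A uniformly sampled history of complex states, used to evaluate delayed
#' terms such as `z(t - tau)` by linear interpolation. Times before `t0`
#' are an error; the integrator itself extends histories with a constant
#' pre-history instead of querying before its start.
#'
#' @param samples Complex states on the uniform grid `t0 + (0:(n-1)) * dt`.
#' @param dt Grid step in seconds.
#' @param t0 Time of the first sample (seconds).
#' @return An object of class `delay_buffer`.
#' @examples
#' b <- delay_buffer(c(0 + 0i, 1 + 0i, 2 + 0i), dt = 0.5)
#' delayed_lookup(b, 0.75)
#' @export
delay_buffer <- function(samples, dt, t0 = 0) {
  if (length(samples) < 1L) abort("`samples` must be non-empty.")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) abort("`dt` must be a positive number.")
  structure(list(samples = as.complex(samples), dt = dt, t0 = t0),
            class = "delay_buffer")
}

#' Interpolated lookup in a delay buffer
#'
#' Linear interpolation between the two bracketing grid samples; exact when
#' the query lies on the grid.
#'
#' @param buffer A [delay_buffer()].
#' @param t_query Query time in seconds (vectorised). Must not precede the
#'   buffer start `t0`.
#' @return Complex value(s) at `t_query`.
#' @export
delayed_lookup <- function(buffer, t_query) {
  stopifnot(inherits(buffer, "delay_buffer"))
  n <- length(buffer$samples)
  tol <- 1e-9 * buffer$dt
  if (any(t_query < buffer$t0 - tol)) {
    abort("history underflow: `t_query` precedes the buffer start `t0`.")
  }
  x <- pmax((t_query - buffer$t0) / buffer$dt, 0)
  i <- pmin(floor(x), n - 1L)
  w <- x - i
  if (any(i + w > n - 1L + tol / buffer$dt)) {
    abort("`t_query` lies beyond the stored history.")
  }
  lo <- buffer$samples[i + 1L]
  hi <- buffer$samples[pmin(i + 2L, n)]
  (1 - w) * lo + w * hi
}

new_trajectory <- function(df, params, spec, extra = list()) {
  out <- as_tibble(df)
  attr(out, "params") <- params
  attr(out, "spec") <- spec
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("sappa_trajectory", class(out))
  out
}

check_step <- function(duration, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) abort("`dt` must be a positive number.")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= dt) {
    abort("`duration` must exceed `dt`.")
  }
}

#' Integrate one oscillator
#'
#' Advances the delay differential equation with a fixed-step 4th-order
#' Runge-Kutta scheme. Delayed terms (`z(t - tau)`) are read from the
#' trajectory history by linear interpolation; the pre-history (`t < 0`) is
#' held constant at the initial state, and `tau` is snapped to the nearest
#' multiple of `dt`. Identical inputs give identical trajectories.
#'
#' @param params An [oscillator_params()].
#' @param spec A [stimulus_spec()] with a single-oscillator feedback mode
#'   (`off`, `constant_self`, `half_cycle_self`) or kind `self_only`/`none`.
#' @param duration Total simulated time in seconds.
#' @param dt Step size in seconds (default 1 ms).
#' @param init_phase Initial phase of `z` in radians (default 0).
#' @param init_magnitude Initial magnitude of `z` (default 1, on the
#'   unforced limit cycle).
#' @return A `sappa_trajectory` tibble with columns `time_s`, `re_z`,
#'   `im_z`, `re_F`, `im_F`, carrying `params` and `spec` as attributes.
#' @examples
#' p <- sappa_params("musician", f = 1)
#' s <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "constant_self")
#' traj <- sappa_integrate(p, s, duration = 5)
#' head(traj)
#' @export
sappa_integrate <- function(params, spec, duration, dt = 1e-3,
                            init_phase = 0, init_magnitude = 1) {
  stopifnot(is_oscillator_params(params), inherits(spec, "stimulus_spec"))
  check_step(duration, dt)
  if (spec$feedback_mode %in% c("duet_alternating", "turn_taking")) {
    abort("use `sappa_integrate_duet()` / `sappa_integrate_turns()` for coupled runs.")
  }
  kind <- match(spec$kind, c("none", "sinusoid", "antiphase_sinusoid",
                             "square_wave", "self_only")) - 1L
  feedback <- match(spec$feedback_mode, c("off", "constant_self", "half_cycle_self")) - 1L
  z0 <- init_magnitude * exp(1i * init_phase)
  res <- integrate_single_cpp(unclass(params), kind, feedback, spec$normalize,
                              spec$fs, duration, dt, Re(z0), Im(z0))
  new_trajectory(
    tibble(time_s = res$time,
           re_z = Re(res$z), im_z = Im(res$z),
           re_F = Re(res$F), im_F = Im(res$F)),
    params, spec, extra = list(dt = dt)
  )
}

#' Integrate a sinusoid-driven duet
#'
#' Two oscillators advance jointly on one grid. Oscillator 1 is driven by
#' `+exp(i 2 pi fs t)` (in-phase role) and oscillator 2 by the negated
#' sinusoid (anti-phase role). With `feedback = "on"` each oscillator
#' additionally receives `A z(k)`, where `k` toggles between self and
#' partner every half stimulus cycle (self first); the combination is
#' normalised to unit magnitude unless `normalize = FALSE`.
#'
#' @param params1,params2 [oscillator_params()] for the two oscillators.
#' @param fs Shared stimulus frequency in Hz.
#' @param feedback `"on"` or `"off"`.
#' @param normalize Normalise the combined input (default `TRUE`).
#' @inheritParams sappa_integrate
#' @return A `sappa_duet_trajectory` tibble with columns `time_s`,
#'   `re_z1`, `im_z1`, `re_F1`, `im_F1`, `re_z2`, `im_z2`, `re_F2`, `im_F2`.
#' @export
sappa_integrate_duet <- function(params1, params2 = params1, fs = 1,
                                 feedback = c("on", "off"), normalize = TRUE,
                                 duration = 20, dt = 1e-3,
                                 init_phase = 0, init_magnitude = 1) {
  stopifnot(is_oscillator_params(params1), is_oscillator_params(params2))
  feedback <- match.arg(feedback)
  check_step(duration, dt)
  z0 <- init_magnitude * exp(1i * init_phase)
  res <- integrate_duet_cpp(unclass(params1), unclass(params2), fs,
                            feedback == "on", isTRUE(normalize),
                            duration, dt, Re(z0), Im(z0))
  out <- tibble(time_s = res$time,
                re_z1 = Re(res$z1), im_z1 = Im(res$z1),
                re_F1 = Re(res$F1), im_F1 = Im(res$F1),
                re_z2 = Re(res$z2), im_z2 = Im(res$z2),
                re_F2 = Re(res$F2), im_F2 = Im(res$F2))
  attr(out, "params1") <- params1
  attr(out, "params2") <- params2
  attr(out, "fs") <- fs
  attr(out, "feedback") <- feedback
  attr(out, "dt") <- dt
  class(out) <- c("sappa_duet_trajectory", class(out))
  out
}

#' Integrate a turn-taking pair
#'
#' Two oscillators with no external sinusoid stimulate each other in
#' alternation. Oscillator 1 initiates: during its turn it receives its own
#' state scaled by `A`, while the passive oscillator receives the active
#' oscillator's state delayed by the transmission latency `tl` (coefficient
#' 1). A turn ends when the active oscillator's unwrapped phase has advanced
#' by `2 pi` since the turn began, at which point the roles swap.
#'
#' @param params1,params2 [oscillator_params()] for initiator and joiner.
#' @param tl Transmission latency in seconds applied to the transmitted
#'   partner signal (self-feedback is never latency-delayed).
#' @param literal_joiner_sign Use the sign-flipped self-input `-A z` for the
#'   joiner's own turns (an alternative, asymmetric reading of the coupling;
#'   default `FALSE`, both oscillators use `A`).
#' @inheritParams sappa_integrate
#' @return A `sappa_turns_trajectory` tibble with per-oscillator state and
#'   input columns; the turn schedule is available via [turn_schedule()].
#' @examples
#' p <- sappa_params("musician", f = 1.5)
#' traj <- sappa_integrate_turns(p, p, tl = 0.02, duration = 10)
#' turn_schedule(traj)
#' @export
sappa_integrate_turns <- function(params1, params2 = params1, tl = 0,
                                  duration = 30, dt = 1e-3,
                                  init_phase = 0, init_magnitude = 1,
                                  literal_joiner_sign = FALSE) {
  stopifnot(is_oscillator_params(params1), is_oscillator_params(params2))
  check_step(duration, dt)
  if (!is.numeric(tl) || length(tl) != 1L || tl < 0) abort("`tl` must be >= 0 seconds.")
  z0 <- init_magnitude * exp(1i * init_phase)
  res <- integrate_turns_cpp(unclass(params1), unclass(params2), tl, duration,
                             dt, Re(z0), Im(z0), isTRUE(literal_joiner_sign))
  out <- tibble(time_s = res$time,
                re_z1 = Re(res$z1), im_z1 = Im(res$z1),
                re_F1 = Re(res$F1), im_F1 = Im(res$F1),
                re_z2 = Re(res$z2), im_z2 = Im(res$z2),
                re_F2 = Re(res$F2), im_F2 = Im(res$F2))
  turns <- tibble(turn = seq_along(res$turn_start),
                  active = res$turn_active,
                  t_start = res$turn_start,
                  t_end = c(res$turn_start[-1], duration))
  attr(out, "params1") <- params1
  attr(out, "params2") <- params2
  attr(out, "tl") <- tl
  attr(out, "dt") <- dt
  attr(out, "turns") <- turns
  class(out) <- c("sappa_turns_trajectory", class(out))
  out
}

#' Turn schedule of a turn-taking run
#'
#' @param trajectory A `sappa_turns_trajectory` from
#'   [sappa_integrate_turns()].
#' @return A tibble with columns `turn`, `active` (oscillator id), `t_start`,
#'   `t_end` (seconds).
#' @export
turn_schedule <- function(trajectory) {
  turns <- attr(trajectory, "turns")
  if (is.null(turns)) abort("`trajectory` has no turn schedule attribute.")
  turns
}

#' Export a trajectory as CSV
#'
#' Writes the trajectory table (`time_s`, `re_z`, `im_z`, `re_F`, `im_F`,
#' and the oscillator-2 columns for coupled runs) with one header row and
#' `.` as the decimal separator.
#'
#' @param trajectory A trajectory tibble from one of the integrators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
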