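#' Peak times of a sampled signal
#'
#' Local maxima found by a discrete sign change of the first difference,
#' refined by fitting a parabola through the three samples around each
#' maximum. Endpoints are excluded; a constant signal yields no peaks.
#'
#' @param signal Real signal values on a uniform grid.
#' @param times Sample times in seconds (uniform spacing).
#' @return Peak times in seconds (possibly empty).
#' @examples
#' t <- seq(0, 3, by = 1e-3)
#' find_peaks(cos(2 * pi * t), t)  # close to 1, 2
#' @export
find_peaks <- function(signal, times) {
  n <- length(signal)
  if (n != length(times)) abort("`signal` and `times` must have equal length.")
  if (n < 3L) abort("need at least 3 samples to locate peaks.")
  dt <- times[2] - times[1]
  i <- 2:(n - 1L)
  is_peak <- signal[i] > signal[i - 1L] & signal[i] >= signal[i + 1L]
  idx <- i[is_peak]
  if (length(idx) == 0L) return(numeric(0))
  ym <- signal[idx - 1L]
  y0 <- signal[idx]
  yp <- signal[idx + 1L]
  den <- ym - 2 * y0 + yp
  offset <- ifelse(abs(den) < .Machine$double.eps * 4, 0, 0.5 * (ym - yp) / den)
  offset <- pmax(pmin(offset, 1), -1)  # never move by more than one sample
  times[idx] + offset * dt
}

#' Cycle-completion times of an oscillator
#'
#' Times at which the oscillator phase `arg(z)` crosses zero upward, i.e.
#' the completion of each cycle (the crest of `Re(z)` for a
#' constant-amplitude oscillation), located by linear interpolation. This
#' event marker is insensitive to the transient amplitude wobbles that can
#' split a single `Re(z)` crest into two local maxima when the input
#' switches discontinuously, and is therefore used as the "clap" event in
#' turn-taking runs.
#'
#' @param re,im Real and imaginary parts of `z` on a uniform grid.
#' @param times Sample times in seconds.
#' @return Crossing times in seconds.
#' @export
cycle_completions <- function(re, im, times) {
  ph <- atan2(im, re)
  n <- length(ph)
  i <- seq_len(n - 1L)
  up <- ph[i] < 0 & ph[i + 1L] >= 0 & (ph[i + 1L] - ph[i]) < pi
  idx <- which(up)
  if (length(idx) == 0L) return(numeric(0))
  w <- -ph[idx] / (ph[idx + 1L] - ph[idx])
  times[idx] + w * (times[idx + 1L] - times[idx])
}

#' Analytic stimulus reference events
#'
#' Peak times of the real part of the external sinusoid `exp(i 2 pi fs t)`
#' lie at integer multiples of the period; valley times are offset by half a
#' period. The square-wave carrier shares the same peak convention.
#'
#' @param fs Stimulus frequency in Hz.
#' @param t_max Last time to include (seconds).
#' @param event `"peak"` or `"valley"`.
#' @param t_min First time to include (seconds, default 0).
#' @return Event times in seconds.
#' @export
stimulus_events <- function(fs, t_max, event = c("peak", "valley"), t_min = 0) {
  event <- match.arg(event)
  period <- 1 / fs
  offset <- if (event == "peak") 0 else period / 2
  k <- seq(floor((t_min - offset) * fs), ceiling((t_max - offset) * fs))
  ev <- k * period + offset
  ev[ev >= t_min & ev <= t_max]
}

#' Steady-state verdict for a per-cycle difference series
#'
#' The series has reached steady state from the first index after which
#' every window of `window` consecutive differences has a range below
#' `tol_s`. The run counts as synchronized when such an onset exists and at
#' least `min_cycles` cycles follow it; otherwise the oscillator is
#' mode-locking or drifting relative to the stimulus.
#'
#' @param differences Per-cycle differences in seconds (at least 8).
#' @param tol_s Range tolerance in seconds (default 1 ms).
#' @param window Window length in cycles (default 5).
#' @param min_cycles Minimum post-onset span in cycles (default 5).
#' @return A list with `synchronized` (flag) and `steady_onset_index`
#'   (1-based; `NA` when never steady).
#' @export
assess_synchrony <- function(differences, tol_s = 1e-3, window = 5L,
                             min_cycles = 5L) {
  n <- length(differences)
  if (n < 8L) abort("need at least 8 per-cycle differences.")
  nw <- n - window + 1L
  ranges <- vapply(seq_len(nw), function(j) {
    w <- differences[j:(j + window - 1L)]
    max(w) - min(w)
  }, numeric(1))
  ok <- ranges < tol_s
  if (!ok[nw]) {
    return(list(synchronized = FALSE, steady_onset_index = NA_integer_))
  }
  bad <- which(!ok)
  onset <- if (length(bad) == 0L) 1L else max(bad) + 1L
  list(synchronized = (n - onset + 1L) >= min_cycles,
       steady_onset_index = onset)
}

new_asynchrony_series <- function(per_cycle, verdict, fs, event) {
  steady <- verdict$steady_onset_index
  if (verdict$synchronized) {
    post <- per_cycle$diff_s[steady:nrow(per_cycle)]
    mean_ms <- mean(post) * 1000
    sd_ms <- sd(post) * 1000
  } else {
    mean_ms <- NA_real_
    sd_ms <- NA_real_
  }
  structure(
    list(per_cycle = per_cycle, steady_onset_index = steady,
         mean_ms = mean_ms, sd_ms = sd_ms,
         synchronized = verdict$synchronized, fs = fs, event = event),
    class = "asynchrony_series"
  )
}

#' Per-cycle asynchrony between model peaks and stimulus events
#'
#' Each stimulus reference event (peak, or valley for anti-phase roles) is
#' paired with the nearest model peak; the per-cycle difference is
#' model peak time minus stimulus event time, so anticipation is negative.
#' The mean and standard deviation (in ms) are computed over the steady
#' part of the series as judged by [assess_synchrony()].
#'
#' @param model_peaks Model peak times in seconds (at least 5).
#' @param fs Stimulus frequency in Hz.
#' @param t_max End of the measurement window (defaults to the last peak).
#' @param event Stimulus reference: `"peak"` or `"valley"`.
#' @param tol_s,window Steady-state criterion, see [assess_synchrony()].
#' @return An `asynchrony_series` object; see [tidy.asynchrony_series()]
#'   and [glance.asynchrony_series()].
#' @export
asynchrony_series <- function(model_peaks, fs, t_max = max(model_peaks),
                              event = c("peak", "valley"),
                              tol_s = 1e-3, window = 5L) {
  event <- match.arg(event)
  if (length(model_peaks) < 5L) {
    abort("measurement failure: fewer than 5 model peaks.")
  }
  ev <- stimulus_events(fs, t_max = t_max, event = event)
  nearest <- vapply(ev, function(e) model_peaks[which.min(abs(model_peaks - e))],
                    numeric(1))
  per_cycle <- tibble(stim_time_s = ev, model_peak_s = nearest,
                      diff_s = nearest - ev)
  verdict <- assess_synchrony(per_cycle$diff_s, tol_s = tol_s, window = window)
  new_asynchrony_series(per_cycle, verdict, fs, event)
}

#' Measure asynchrony from a trajectory
#'
#' Finds the peaks of `Re(z)` and pairs them with the analytic stimulus
#' reference events. For duet runs, `oscillator = 2` with
#' `event = "valley"` measures the anti-phase oscillator against the
#' stimulus valleys.
#'
#' @param trajectory A trajectory tibble from [sappa_integrate()] or
#'   [sappa_integrate_duet()].
#' @param oscillator 1 or 2 (coupled runs only).
#' @param event `"peak"` or `"valley"` stimulus reference.
#' @param fs Stimulus frequency; defaults to the frequency recorded in the
#'   trajectory attributes.
#' @inheritParams asynchrony_series
#' @return An `asynchrony_series` object.
#' @examples
#' p <- sappa_params("nonmusician", f = 1)
#' s <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "constant_self")
#' a <- measure_asynchrony(sappa_integrate(p, s, duration = 20))
#' glance(a)
#' @export
measure_asynchrony <- function(trajectory, oscillator = 1L,
                               event = c("peak", "valley"), fs = NULL,
                               tol_s = 1e-3, window = 5L) {
  event <- match.arg(event)
  if (is.null(fs)) {
    spec <- attr(trajectory, "spec")
    fs <- if (!is.null(spec)) spec$fs else attr(trajectory, "fs")
    if (is.null(fs)) abort("supply `fs`: the trajectory records no stimulus frequency.")
  }
  col <- if ("re_z" %in% names(trajectory)) {
    "re_z"
  } else {
    paste0("re_z", oscillator)
  }
  peaks <- find_peaks(trajectory[[col]], trajectory$time_s)
  if (length(peaks) == 0L) abort("measurement failure: no model peaks found.")
  # pair only stimulus events up to the last model peak; later events have
  # no bracketing peak and would pick up a truncation artifact
  asynchrony_series(peaks, fs = fs, t_max = max(peaks),
                    event = event, tol_s = tol_s, window = window)
}

#' @export
print.asynchrony_series <- function(x, ...) {
  cat("<asynchrony_series>\n")
  if (x$synchronized) {
    cat(sprintf("  synchronized; mean = %.3f ms (sd %.3f) over cycles %d..%d\n",
                x$mean_ms, x$sd_ms, x$steady_onset_index, nrow(x$per_cycle)))
  } else {
    cat("  NOT synchronized (no steady state reached)\n")
  }
  invisible(x)
}

#' Lead/lag statistic for turn-taking runs
#'
#' For each interior turn, the statistic
#' `L = (a(1) - b(1)) + (b(2) - a(2))` sums the handover lags at the two
#' boundaries flanking the turn: `a(1)` is the first clap of the current
#' turn-taker within its turn and `b(1)` the last clap of the previous
#' turn-taker within the previous turn; `b(2)` is the first clap of the
#' next turn-taker within the next turn and `a(2)` the last clap of the
#' current turn-taker within its turn. Claps are the `Re(z)` peak times of
#' each oscillator; because turn boundaries fall at the active
#' oscillator's cycle completion, clap selection tolerates a
#' quarter-period guard band around each boundary. `L` is converted to a
#' fraction of a 90 bpm beat as `-90 * L_ms / (60 * 1000)`; a negative
#' fraction means the passive oscillator lagged behind the active one.
#'
#' @param claps1,claps2 Clap (peak) times in seconds for oscillators 1 and 2.
#' @param turns Turn schedule tibble with columns `turn`, `active`,
#'   `t_start`, `t_end` (see [turn_schedule()]).
#' @param tl_ms Transmission latency in ms, recorded in the result.
#' @return A `leadlag_result` with a per-turn tibble (`turn`, `active`,
#'   `L_s`, `L_ms`, `fraction`, `percent`) and the mean fraction.
#' @export
lead_lag <- function(claps1, claps2, turns, tl_ms = NA_real_) {
  if (nrow(turns) < 3L) abort("insufficient turns: need at least 3.")
  claps <- list(claps1, claps2)
  q <- stats::median(diff(turns$t_start)) / 4  # quarter-period guard band
  nearest <- function(x, t) x[which.min(abs(x - t))]
  first_after <- function(x, t) {
    c <- x[x > t]
    if (length(c) == 0L) nearest(x, t) else min(c)
  }
  last_before <- function(x, t) {
    c <- x[x <= t]
    if (length(c) == 0L) nearest(x, t) else max(c)
  }
  ks <- 2:(nrow(turns) - 1L)
  rows <- lapply(ks, function(k) {
    m <- turns$active[k]
    prev <- turns$active[k - 1L]
    nxt <- turns$active[k + 1L]
    t_on <- turns$t_start[k]
    t_off <- turns$t_end[k]
    a1 <- first_after(claps[[m]], t_on - q)   # first clap of the turn-taker
    b1 <- last_before(claps[[prev]], t_on + q) # last clap of the previous taker
    b2 <- first_after(claps[[nxt]], t_off - q) # first clap of the next taker
    a2 <- last_before(claps[[m]], t_off + q)  # last clap of the turn-taker
    L <- (a1 - b1) + (b2 - a2)
    tibble(turn = turns$turn[k], active = m, L_s = L)
  })
  per_turn <- bind_rows(rows)
  per_turn$L_ms <- per_turn$L_s * 1000
  per_turn$fraction <- -90 * per_turn$L_ms / (60 * 1000)
  per_turn$percent <- per_turn$fraction * 100
  structure(
    list(per_turn = per_turn, tl_ms = tl_ms,
         mean_fraction = mean(per_turn$fraction)),
    class = "leadlag_result"
  )
}

#' @export
print.leadlag_result <- function(x, ...) {
  cat(sprintf("<leadlag_result> tl = %s ms, %d turns, mean fraction = %.4f\n",
              format(x$tl_ms), nrow(x$per_turn), x$mean_fraction))
  invisible(x)
}
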