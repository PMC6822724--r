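#' Stimulus specification
#'
#' Describes the input `F` driving an oscillator. The periodic carrier is a
#' unit complex sinusoid `exp(i 2 pi fs t)` (or its negation, or a square
#' wave); feedback modes add the oscillator's own or a partner's
#' instantaneous activity:
#'
#' * `off`: carrier only.
#' * `constant_self`: `(carrier + A z) / |carrier + A z|` throughout
#'   (the unit-magnitude normalised combination; set `normalize = FALSE`
#'   to skip the normalisation).
#' * `half_cycle_self`: carrier alone while the stimulus phase is in
#'   `[0, pi)`, the combined form while it is in `[pi, 2 pi)`.
#' * `duet_alternating`: carrier plus `A z(k)`, where `k` toggles between
#'   self and partner every half stimulus cycle (self first).
#' * `turn_taking`: no carrier; `A z_self` while active, the partner's
#'   latency-delayed state (coefficient 1) while passive.
#'
#' @param kind Carrier kind: `"sinusoid"`, `"antiphase_sinusoid"`,
#'   `"square_wave"`, `"self_only"`, or `"none"`.
#' @param fs Stimulus frequency in Hz (ignored for `"none"`/`"self_only"`).
#' @param feedback_mode One of `"off"`, `"constant_self"`,
#'   `"half_cycle_self"`, `"duet_alternating"`, `"turn_taking"`.
#' @param normalize Apply the unit-magnitude normalisation when the carrier
#'   is combined with an oscillator signal. Defaults to `TRUE`, the form the
#'   model uses whenever a sinusoid and `A z` are summed.
#' @param tl Transmission latency in seconds; only meaningful (and only
#'   allowed non-zero) for `feedback_mode = "turn_taking"`.
#'
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec("sinusoid", fs = 1)
#' stimulus_spec("sinusoid", fs = 1, feedback_mode = "constant_self")
#' @export
stimulus_spec <- function(kind = c("sinusoid", "antiphase_sinusoid", "square_wave",
                                   "self_only", "none"),
                          fs = 1,
                          feedback_mode = c("off", "constant_self", "half_cycle_self",
                                            "duet_alternating", "turn_taking"),
                          normalize = TRUE, tl = 0) {
  kind <- match.arg(kind)
  feedback_mode <- match.arg(feedback_mode)
  if (kind %in% c("sinusoid", "antiphase_sinusoid", "square_wave")) {
    if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
      abort("`fs` must be a single positive number (Hz) for a periodic carrier.")
    }
  }
  if (!is.numeric(tl) || length(tl) != 1L || !is.finite(tl) || tl < 0) {
    abort("`tl` must be a single non-negative number (seconds).")
  }
  if (tl > 0 && feedback_mode != "turn_taking") {
    abort("`tl` must be 0 unless `feedback_mode` is \"turn_taking\".")
  }
  structure(
    list(kind = kind, fs = fs, feedback_mode = feedback_mode,
         normalize = isTRUE(normalize), tl = tl),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> kind = %s, fs = %g Hz, feedback = %s, normalize = %s, tl = %g s\n",
              x$kind, x$fs, x$feedback_mode, x$normalize, x$tl))
  invisible(x)
}

carrier_value <- function(t, kind, fs) {
  switch(kind,
    sinusoid = exp(1i * 2 * pi * fs * t),
    antiphase_sinusoid = -exp(1i * 2 * pi * fs * t),
    square_wave = complex(real = ifelse(cos(2 * pi * fs * t) >= 0, 1, -1),
                          imaginary = 0),
    none = ,
    self_only = rep(0 + 0i, length(t))
  )
}

#' Evaluate the stimulus input F
#'
#' Pure evaluation of the input `F` at time `t` for a given stimulus
#' specification and oscillator state(s). This is the reference
#' implementation of the input functions; the compiled integrator mirrors
#' it internally.
#'
#' @param t Time in seconds (vectorised).
#' @param spec A [stimulus_spec()].
#' @param params An [oscillator_params()] supplying the coefficient `A`.
#' @param z_self Oscillator's own instantaneous state (complex; recycled).
#' @param z_partner Partner state for `duet_alternating` / `turn_taking`
#'   modes. For turn taking the caller supplies the latency-delayed value.
#' @param active For `turn_taking`: is this oscillator currently active?
#' @return Complex input value(s) `F`.
#' @examples
#' stimulus_input(0, stimulus_spec("sinusoid", fs = 1),
#'                oscillator_params(f = 1))
#' @export
stimulus_input <- function(t, spec, params, z_self = 0 + 0i, z_partner = NULL,
                           active = TRUE) {
  stopifnot(inherits(spec, "stimulus_spec"), is_oscillator_params(params))
  A <- params$A
  mode <- spec$feedback_mode
  needs_partner <- mode %in% c("duet_alternating", "turn_taking")
  if (needs_partner && is.null(z_partner) && !(mode == "turn_taking" && active)) {
    abort("`z_partner` is required for duet_alternating / passive turn_taking input.")
  }
  if (!needs_partner && !is.null(z_partner)) {
    abort("`z_partner` is only meaningful for duet_alternating / turn_taking modes.")
  }
  if (mode == "turn_taking") {
    return(if (active) A * (z_self + 0 * t) else (z_partner + 0 * t))
  }
  if (spec$kind == "self_only") return(A * (z_self + 0 * t))
  cv <- carrier_value(t, spec$kind, spec$fs)
  if (mode == "off" || spec$kind == "none") return(cv)
  frac <- (spec$fs * t) %% 1
  combine <- switch(mode,
    constant_self = rep(TRUE, length(t)),
    half_cycle_self = frac >= 0.5,
    duet_alternating = rep(TRUE, length(t))
  )
  zk <- if (mode == "duet_alternating") {
    ifelse(frac < 0.5, z_self + 0 * t, z_partner + 0 * t)
  } else {
    z_self + 0 * t
  }
  u <- cv + A * zk
  if (spec$normalize) {
    m <- Mod(u)
    if (any(combine & m < 1e-12)) {
      abort("degenerate stimulus input: zero magnitude before normalization.")
    }
    u <- ifelse(combine, u / m, u)
  }
  ifelse(combine, u, cv)
}
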