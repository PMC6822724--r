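#' Oscillator parameters
#'
#' Builds the parameter set of the canonical Hopf oscillator with delayed
#' recurrent feedback. The oscillator state `z` evolves as
#' \deqn{\frac{1}{f}\dot z = z\left(\alpha + i2\pi + \beta_1 |z|^2 +
#'   \frac{\epsilon \beta_2 |z|^4}{1 - \epsilon |z|^2}\right) + F -
#'   \frac{D}{f} z(t - \tau)}
#' where `F` is the input (see [stimulus_spec()]). The SAPPA configuration
#' fixes `alpha = 1`, `beta1 = -1`, `beta2 = 0`, `epsilon = 0`, so that the
#' unforced, feedback-free oscillator settles on the unit circle.
#'
#' @param f Natural frequency in Hz (must be positive).
#' @param D Amplitude of the delayed recurrent feedback (dimensionless, >= 0).
#' @param tau Recurrent feedback delay in seconds (>= 0).
#' @param A Self/partner input coefficient used when the oscillator's own (or
#'   its partner's) activity enters the input `F`. Negative values are the
#'   usual convention (recurrent feedback terms are negative).
#' @param alpha Growth parameter of the Hopf normal form.
#' @param beta1 First nonlinearity coefficient.
#' @param beta2 Second nonlinearity coefficient (0 in the SAPPA configuration).
#' @param epsilon Degree of higher-order nonlinear coupling (0 in the SAPPA
#'   configuration). When positive, trajectories must keep
#'   `epsilon * |z|^2 < 1`.
#' @param delta Frequency detuning offset in Hz added to `f`; a positive value
#'   makes the oscillator run slightly fast relative to a stimulus at `f`.
#'
#' @return An object of class `oscillator_params` (a named list).
#' @seealso [sappa_params()] for the musician / non-musician presets.
#' @examples
#' oscillator_params(f = 1, D = 0.36, tau = 0.222)
#' @export
oscillator_params <- function(f, D = 0, tau = 0, A = -0.5, alpha = 1,
                              beta1 = -1, beta2 = 0, epsilon = 0, delta = 0) {
  for (nm in c("f", "D", "tau", "A", "alpha", "beta1", "beta2", "epsilon", "delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (f <= 0) abort("`f` must be positive (Hz).")
  if (D < 0) abort("`D` must be >= 0.")
  if (tau < 0) abort("`tau` must be >= 0 (seconds).")
  structure(
    list(alpha = alpha, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         f = f, D = D, tau = tau, A = A, delta = delta),
    class = "oscillator_params"
  )
}

#' Musician / non-musician oscillator presets
#'
#' The two behavioural profiles differ only in the amplitude `D` of the
#' delayed recurrent feedback: `D = 0.05` for the musician profile and
#' `D = 0.36` for the non-musician profile. Both share `tau = 0.222` s and
#' `A = -0.5`.
#'
#' @param profile `"musician"` or `"nonmusician"`.
#' @param f Natural frequency in Hz.
#' @param delta Frequency detuning offset in Hz (default 0).
#' @return An [oscillator_params()] object.
#' @examples
#' sappa_params("musician", f = 1)
#' sappa_params("nonmusician", f = 1.5)
#' @export
sappa_params <- function(profile = c("musician", "nonmusician"), f = 1, delta = 0) {
  profile <- match.arg(profile)
  D <- if (profile == "musician") 0.05 else 0.36
  oscillator_params(f = f, D = D, tau = 0.222, A = -0.5, delta = delta)
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params>\n")
  cat(sprintf("  f = %g Hz (delta = %g), D = %g, tau = %g s, A = %g\n",
              x$f, x$delta, x$D, x$tau, x$A))
  cat(sprintf("  alpha = %g, beta1 = %g, beta2 = %g, epsilon = %g\n",
              x$alpha, x$beta1, x$beta2, x$epsilon))
  invisible(x)
}

is_oscillator_params <- function(x) inherits(x, "oscillator_params")
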