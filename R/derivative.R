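#' Oscillator time derivative
#'
#' Right-hand side of the delay differential equation governing the
#' oscillator: the Hopf normal form (optionally with the higher-order
#' nonlinearity) driven by an input `F` and damped by its own delayed
#' state. The value returned is already multiplied through by the
#' effective frequency, i.e.
#' \deqn{\dot z = (f + \Delta)\left[z\left(\alpha + i2\pi + \beta_1|z|^2 +
#'   \frac{\epsilon\beta_2|z|^4}{1-\epsilon|z|^2}\right) + F\right] -
#'   D\, z(t-\tau).}
#'
#' The function is pure: the caller (normally the integrator) supplies the
#' delayed state `z_delayed = z(t - tau)`.
#'
#' @param z Current oscillator state (complex; vectorised).
#' @param z_delayed Delayed state `z(t - tau)` (complex; recycled).
#' @param F_input Input value `F` (complex; recycled).
#' @param params An [oscillator_params()].
#' @return `dz/dt` (complex).
#' @examples
#' p <- oscillator_params(f = 1, D = 0)
#' sappa_derivative(1 + 0i, 0i, 0i, p)  # i*2*pi: pure rotation on the unit circle
#' @export
sappa_derivative <- function(z, z_delayed, F_input, params) {
  stopifnot(is_oscillator_params(params))
  r2 <- Mod(z)^2
  nl <- params$alpha + 1i * 2 * pi + params$beta1 * r2
  if (params$epsilon != 0) {
    den <- 1 - params$epsilon * r2
    if (any(den <= 0)) {
      abort("singular denominator: epsilon * |z|^2 >= 1.")
    }
    nl <- nl + params$epsilon * params$beta2 * r2^2 / den
  }
  (params$f + params$delta) * (z * nl + F_input) - params$D * z_delayed
}
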