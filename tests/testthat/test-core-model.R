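test_that("parameter constructor validates and presets are as published", {
  p <- sappa_params("musician", f = 1)
  expect_equal(p$alpha, 1)
  expect_equal(p$beta1, -1)
  expect_equal(p$beta2, 0)
  expect_equal(p$epsilon, 0)
  expect_equal(p$D, 0.05)
  expect_equal(p$tau, 0.222)
  expect_equal(p$A, -0.5)
  expect_equal(sappa_params("nonmusician")$D, 0.36)

  expect_error(oscillator_params(f = 0), "positive")
  expect_error(oscillator_params(f = 1, D = -0.1), ">= 0")
  expect_error(oscillator_params(f = 1, tau = -1), ">= 0")
  expect_error(oscillator_params(f = NA_real_), "finite")
})

test_that("derivative matches hand-evaluated cases", {
  p0 <- oscillator_params(f = 1, D = 0)
  # origin is an equilibrium of the unforced system
  expect_equal(sappa_derivative(0 + 0i, 0i, 0i, p0), 0 + 0i)
  # on the unit circle the radial terms cancel, leaving pure rotation
  expect_equal(sappa_derivative(1 + 0i, 0i, 0i, p0), 2i * pi)
  # independently hand-evaluated: z=0.5, z_tau=i, F=1, D=0.36, f=0.5
  p1 <- oscillator_params(f = 0.5, D = 0.36, tau = 0.1)
  got <- sappa_derivative(0.5 + 0i, 0 + 1i, 1 + 0i, p1)
  expect_equal(Re(got), 0.6875, tolerance = 1e-12)
  expect_equal(Im(got), 1.2108, tolerance = 1e-4)
})

test_that("derivative is linear in the input and in the delayed state", {
  p <- oscillator_params(f = 1.3, D = 0.4, tau = 0.2)
  z <- 0.3 - 0.8i
  base <- sappa_derivative(z, 0i, 0i, p)
  f1 <- sappa_derivative(z, 0i, 0.7 + 0.2i, p) - base
  f2 <- sappa_derivative(z, 0i, 1.4 + 0.4i, p) - base
  expect_equal(2 * f1, f2)
  d1 <- sappa_derivative(z, 0.5i, 0i, p) - base
  d2 <- sappa_derivative(z, 1.0i, 0i, p) - base
  expect_equal(2 * d1, d2)
})

test_that("higher-order nonlinearity guards its singular denominator", {
  p <- oscillator_params(f = 1, epsilon = 1, beta2 = 0.5)
  expect_error(sappa_derivative(1 + 0i, 0i, 0i, p), "singular")
  # below the singularity the term evaluates finitely
  expect_true(is.finite(Mod(sappa_derivative(0.5 + 0i, 0i, 0i, p))))
})

test_that("stimulus input reproduces the defined forms", {
  p <- oscillator_params(f = 1, A = -0.5)
  s_off <- stimulus_spec("sinusoid", fs = 1)
  expect_equal(stimulus_input(0, s_off, p), 1 + 0i)
  s_on <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "constant_self")
  # with zero state the combined form reduces to the bare sinusoid
  expect_equal(stimulus_input(0, s_on, p, z_self = 0 + 0i), 1 + 0i)
  # hand evaluation of the normalised combination at z = i, A = -0.5
  got <- stimulus_input(0, s_on, p, z_self = 0 + 1i)
  expect_equal(got, (1 - 0.5i) / Mod(1 - 0.5i), tolerance = 1e-12)
  expect_equal(Re(got), 0.8944, tolerance = 1e-4)
  expect_equal(Im(got), -0.4472, tolerance = 1e-4)
})

test_that("normalized inputs have unit magnitude away from the degenerate point", {
  p <- oscillator_params(f = 1, A = -0.5)
  s_on <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "constant_self")
  ts <- seq(0, 2, by = 0.05)
  zs <- 0.9 * exp(1i * (2 * pi * ts + 0.3))
  vals <- stimulus_input(ts, s_on, p, z_self = zs)
  expect_equal(Mod(vals), rep(1, length(ts)), tolerance = 1e-12)
  # the degenerate zero-denominator point is reported as an error
  pA <- oscillator_params(f = 1, A = -1)
  expect_error(stimulus_input(0, s_on, pA, z_self = 1 + 0i), "degenerate")
})

test_that("half-cycle feedback switches exactly at the stimulus half period", {
  p <- oscillator_params(f = 1, A = -0.5)
  s_half <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "half_cycle_self")
  s_off <- stimulus_spec("sinusoid", fs = 1)
  s_on <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "constant_self")
  z <- 0.4 + 0.6i
  t_first <- c(0, 0.2, 0.49, 1.1, 2.3)
  t_second <- c(0.5, 0.7, 0.99, 1.6, 2.8)
  expect_equal(stimulus_input(t_first, s_half, p, z_self = z),
               stimulus_input(t_first, s_off, p))
  expect_equal(stimulus_input(t_second, s_half, p, z_self = z),
               stimulus_input(t_second, s_on, p, z_self = z))
})

test_that("square wave carrier is peak-aligned with the sinusoid", {
  p <- oscillator_params(f = 1)
  s_sq <- stimulus_spec("square_wave", fs = 1)
  expect_equal(stimulus_input(0, s_sq, p), 1 + 0i)
  expect_equal(stimulus_input(0.3, s_sq, p), -1 + 0i)
  expect_equal(stimulus_input(0.9, s_sq, p), 1 + 0i)
  expect_equal(Im(stimulus_input(seq(0, 3, by = 0.01), s_sq, p)),
               rep(0, 301))
})

test_that("stimulus spec rejects inconsistent fields", {
  expect_error(stimulus_spec("sinusoid", fs = 0), "positive")
  expect_error(stimulus_spec("sinusoid", fs = 1, tl = 0.01), "turn_taking")
  p <- oscillator_params(f = 1)
  s <- stimulus_spec("sinusoid", fs = 1)
  expect_error(stimulus_input(0, s, p, z_partner = 1 + 0i), "duet_alternating")
})
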