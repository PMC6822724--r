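test_that("delay buffer lookup interpolates linearly and errors on underflow", {
  b <- delay_buffer(c(1 + 1i, 2 + 0i, 3 - 1i), dt = 0.5, t0 = 0)
  # on-grid lookups return the stored samples
  expect_equal(delayed_lookup(b, 0), 1 + 1i)
  expect_equal(delayed_lookup(b, 0.5), 2 + 0i)
  expect_equal(delayed_lookup(b, 1), 3 - 1i)
  # a real ramp interpolates to the midpoint value
  ramp <- delay_buffer(as.complex(seq(0, 1, by = 0.25)), dt = 0.25)
  expect_equal(delayed_lookup(ramp, 0.375), 0.375 + 0i)
  # a constant history returns the constant everywhere
  const <- delay_buffer(rep(4 + 2i, 5), dt = 0.1)
  expect_equal(delayed_lookup(const, c(0.05, 0.21, 0.4)), rep(4 + 2i, 3))
  expect_error(delayed_lookup(b, -0.1), "underflow")
})

test_that("unforced oscillator settles on the unit circle at its natural frequency", {
  p <- oscillator_params(f = 1, D = 0)
  tr <- sappa_integrate(p, stimulus_spec("none"), duration = 20,
                        init_magnitude = 0.5)
  mod <- sqrt(tr$re_z^2 + tr$im_z^2)
  expect_equal(mean(mod[tr$time_s >= 15]), 1, tolerance = 1e-6)
  pk <- find_peaks(tr$re_z, tr$time_s)
  expect_equal(diff(tail(pk, 5)), rep(1, 4), tolerance = 1e-4)
})

test_that("without delayed feedback the driven oscillator locks with zero asynchrony", {
  p <- oscillator_params(f = 1, D = 0)
  g <- quick_asynchrony(p, drive_off())
  expect_true(g$synchronized)
  expect_lt(abs(g$mean_asynchrony_ms), 0.1)
})

test_that("repeated runs are byte-identical", {
  p <- nonmusician_1hz()
  t1 <- sappa_integrate(p, drive_on(), duration = 5)
  t2 <- sappa_integrate(p, drive_on(), duration = 5)
  expect_identical(t1, t2)
  d1 <- sappa_integrate_turns(p, p, tl = 0.02, duration = 5)
  d2 <- sappa_integrate_turns(p, p, tl = 0.02, duration = 5)
  expect_identical(d1, d2)
})

test_that("halving the step shrinks the terminal error monotonically at order >= 2", {
  p <- nonmusician_1hz()
  s <- drive_on()
  term <- function(dt) {
    tr <- sappa_integrate(p, s, duration = 5, dt = dt)
    complex(real = tail(tr$re_z, 1), imaginary = tail(tr$im_z, 1))
  }
  ref <- term(0.000125)
  errs <- vapply(c(0.002, 0.001, 0.0005), function(h) Mod(term(h) - ref),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[2], 2^2 * 0.8)
  expect_gt(errs[2] / errs[3], 2^2 * 0.8)
})

test_that("terminal state agrees with an independent delay-equation solver", {
  library(deSolve)
  p <- nonmusician_1hz()
  s <- drive_on()
  tr <- sappa_integrate(p, s, duration = 10)
  ours <- complex(real = tail(tr$re_z, 1), imaginary = tail(tr$im_z, 1))
  deriv <- function(t, y, parms) {
    z <- complex(real = y[1], imaginary = y[2])
    zd <- if (t < parms$tau) 1 + 0i else {
      v <- lagvalue(t - parms$tau)
      complex(real = v[1], imaginary = v[2])
    }
    u <- exp(1i * 2 * pi * t) + parms$A * z
    u <- u / Mod(u)
    dz <- parms$f * (z * (1 + 2i * pi - Mod(z)^2) + u) - parms$D * zd
    list(c(Re(dz), Im(dz)))
  }
  out <- dede(y = c(1, 0), times = seq(0, 10, by = 1e-3), func = deriv,
              parms = list(f = p$f, D = p$D, tau = p$tau, A = p$A))
  theirs <- complex(real = tail(out[, 2], 1), imaginary = tail(out[, 3], 1))
  expect_lt(Mod(ours - theirs), 1e-3)
})

test_that("state stays bounded for unit-magnitude inputs across a (D, tau, A) grid", {
  for (D in c(0.05, 0.5, 1)) {
    for (tau in c(0.05, 0.25, 0.5)) {
      for (A in c(-0.5, 0.5)) {
        p <- oscillator_params(f = 1, D = D, tau = tau, A = A)
        tr <- sappa_integrate(p, drive_on(), duration = 10)
        expect_lt(max(sqrt(tr$re_z^2 + tr$im_z^2)), 2)
      }
    }
  }
})

test_that("divergent dynamics raise a blow-up error naming the failure time", {
  p <- oscillator_params(f = 1, D = 0, beta1 = 1, alpha = 5)
  expect_error(sappa_integrate(p, stimulus_spec("none"), duration = 10),
               "blew up.*t =")
})

test_that("the stored input trace matches the reference stimulus functions", {
  p <- musician_1hz()
  s <- stimulus_spec("sinusoid", fs = 1, feedback_mode = "half_cycle_self")
  tr <- sappa_integrate(p, s, duration = 3)
  z <- complex(real = tr$re_z, imaginary = tr$im_z)
  Fref <- stimulus_input(tr$time_s, s, p, z_self = z)
  expect_equal(complex(real = tr$re_F, imaginary = tr$im_F), Fref,
               tolerance = 1e-12)
})

test_that("duet feedback alternates self and partner twice per stimulus period", {
  p <- musician_1hz()
  tr <- sappa_integrate_duet(p, p, fs = 1, feedback = "on", duration = 4)
  z1 <- complex(real = tr$re_z1, imaginary = tr$im_z1)
  z2 <- complex(real = tr$re_z2, imaginary = tr$im_z2)
  F1 <- complex(real = tr$re_F1, imaginary = tr$im_F1)
  carrier <- exp(1i * 2 * pi * tr$time_s)
  frac <- (tr$time_s) %% 1
  zk <- ifelse(frac < 0.5, z1, z2)
  expected <- (carrier + p$A * zk) / Mod(carrier + p$A * zk)
  expect_equal(F1, expected, tolerance = 1e-12)
  # the self/partner toggle flips exactly twice per stimulus period
  toggles <- sum(diff(frac < 0.5) != 0)
  expect_equal(toggles, 2 * 4)
})

test_that("trajectory export writes the documented columns", {
  p <- musician_1hz()
  tr <- sappa_integrate(p, drive_off(), duration = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  got <- utils::read.csv(path)
  expect_named(got, c("time_s", "re_z", "im_z", "re_F", "im_F"))
  expect_equal(nrow(got), nrow(tr))
})
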