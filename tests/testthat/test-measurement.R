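test_that("peak finding locates cosine maxima to sub-sample accuracy", {
  t <- seq(0, 3, by = 1e-3)
  pk <- find_peaks(cos(2 * pi * t), t)
  expect_equal(pk, c(1, 2), tolerance = 5e-4)
  expect_length(find_peaks(rep(1, 100), seq_len(100) / 100), 0)
})

test_that("parabolic refinement recovers an off-grid apex and stays local", {
  t <- seq(0, 1, by = 0.01)
  apex <- 0.50123
  y <- -(t - apex)^2
  pk <- find_peaks(y, t)
  expect_equal(pk, apex, tolerance = 1e-4)
  # refinement never moves a peak by more than one sample interval
  y2 <- sin(2 * pi * 3 * t) + 0.1 * t
  raw_idx <- which(diff(sign(diff(y2))) < 0) + 1L
  pk2 <- find_peaks(y2, t)
  expect_true(all(abs(pk2 - t[raw_idx]) <= 0.01 + 1e-12))
})

test_that("cycle completions mark upward phase crossings once per cycle", {
  t <- seq(0, 4.5, by = 1e-3)
  z <- (1 + 0.3 * sin(2 * pi * 5 * t)) * exp(1i * 2 * pi * t)  # wobbly amplitude
  cc <- cycle_completions(Re(z), Im(z), t)
  expect_equal(cc, 1:4, tolerance = 1e-6)
})

test_that("analytic stimulus events fall at period multiples and half-period offsets", {
  expect_equal(stimulus_events(1, t_max = 3.2), 0:3)
  expect_equal(stimulus_events(1, t_max = 3.2, event = "valley"),
               c(0.5, 1.5, 2.5))
  expect_equal(stimulus_events(2, t_max = 1.1, t_min = 0.2), c(0.5, 1))
})

test_that("steady-state assessment distinguishes constant, drifting and converging series", {
  const <- rep(-0.01, 10)
  v <- assess_synchrony(const)
  expect_true(v$synchronized)
  expect_equal(v$steady_onset_index, 1L)

  drift <- seq(0, by = 1e-3, length.out = 20)  # 1 ms per cycle forever
  expect_false(assess_synchrony(drift)$synchronized)

  conv <- -0.05 * exp(-(0:14))
  v2 <- assess_synchrony(conv)
  # onset equals the first window whose range is below tolerance,
  # computed directly
  ranges <- vapply(1:11, function(j) diff(range(conv[j:(j + 4)])), numeric(1))
  expect_equal(v2$steady_onset_index, min(which(ranges < 1e-3)))
  expect_true(v2$synchronized)
})

test_that("asynchrony pairing reproduces constructed event-train offsets", {
  peaks <- 0:19
  a0 <- asynchrony_series(peaks, fs = 1)
  expect_equal(a0$mean_ms, 0)
  expect_true(a0$synchronized)

  a_shift <- asynchrony_series(peaks - 0.05, fs = 1, t_max = 19)
  expect_equal(a_shift$mean_ms, -50)

  # an anti-phase train scores zero against valleys but half a period
  # against peaks
  anti <- 0:19 + 0.5
  expect_equal(asynchrony_series(anti, fs = 1, event = "valley")$mean_ms, 0)
  a_peak <- asynchrony_series(anti, fs = 1, event = "peak")
  expect_equal(mean(abs(a_peak$per_cycle$diff_s)), 0.5, tolerance = 1e-9)

  expect_error(asynchrony_series(c(1, 2), fs = 1), "fewer than 5")
})

test_that("mean asynchrony is shift-equivariant within a quarter period", {
  peaks <- 0:19 - 0.02
  base <- asynchrony_series(peaks, fs = 1, t_max = 19)$mean_ms
  for (c_s in c(-0.2, -0.1, 0.05, 0.2)) {
    shifted <- asynchrony_series(peaks + c_s, fs = 1, t_max = 19)$mean_ms
    expect_equal(shifted - base, c_s * 1000, tolerance = 1e-9)
  }
})

test_that("lead/lag statistic evaluates the turn-boundary differences", {
  turns <- tibble::tibble(turn = 1:3, active = c(1L, 2L, 1L),
                          t_start = c(0, 1, 2), t_end = c(1, 2, 3))
  # a(1)-b(1) = 10 ms, b(2)-a(2) = -5 ms -> L = 5 ms, fraction -0.0075
  ll <- lead_lag(claps1 = c(1.000, 2.005), claps2 = c(1.010, 2.010), turns)
  expect_equal(ll$per_turn$L_ms, 5, tolerance = 1e-9)
  expect_equal(ll$per_turn$fraction, -0.0075, tolerance = 1e-9)
  # a(1)-b(1) = -20 ms, b(2)-a(2) = -20 ms -> L = -40 ms, fraction +0.06
  ll2 <- lead_lag(claps1 = c(1.000, 1.980), claps2 = c(0.980, 2.000), turns)
  expect_equal(ll2$per_turn$L_ms, -40, tolerance = 1e-9)
  expect_equal(ll2$per_turn$fraction, 0.06, tolerance = 1e-9)
  # perfectly abutting turns give L = 0
  ll3 <- lead_lag(claps1 = c(1, 2), claps2 = c(1, 2), turns)
  expect_equal(ll3$per_turn$L_ms, 0)
  expect_error(lead_lag(1:2, 1:2, turns[1:2, ]), "insufficient turns")
})

test_that("beat-fraction conversion is exactly linear in L", {
  turns <- tibble::tibble(turn = 1:3, active = c(1L, 2L, 1L),
                          t_start = c(0, 1, 2), t_end = c(1, 2, 3))
  for (lag in c(-0.03, 0, 0.012, 0.04)) {
    ll <- lead_lag(claps1 = c(1, 2 + lag), claps2 = c(1 + lag, 2), turns)
    expect_equal(ll$per_turn$fraction, -90 * (2 * lag * 1000) / 60000,
                 tolerance = 1e-9)
  }
})
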