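test_that("a sweep cell equals a standalone integrate-and-measure run", {
  sw <- sweep_asynchrony(A = -0.5, f = 1, D_grid = 0.36, tau_grid = 0.222,
                         cycles = 15)
  p <- oscillator_params(f = 1, D = 0.36, tau = 0.222, A = -0.5)
  standalone <- quick_asynchrony(p, drive_on(), duration = 15)
  expect_equal(sw$asynchrony_ms, standalone$mean_asynchrony_ms)
})

test_that("without delayed feedback the sweep row is flat at zero asynchrony", {
  sw <- sweep_asynchrony(A = 0, f = 1, D_grid = 0,
                         tau_grid = c(0, 0.1, 0.3, 0.5), cycles = 15)
  expect_true(all(!sw$failed))
  expect_true(all(abs(sw$asynchrony_ms) < 0.1))
})

test_that("failed cells carry no asynchrony value and the matrix layout matches", {
  sw <- sweep_asynchrony(A = 1, f = 1, D_grid = c(0.2, 1),
                         tau_grid = c(0.1, 0.3), cycles = 20)
  expect_true(any(sw$failed))
  expect_true(all(is.na(sw$asynchrony_ms[sw$failed])))
  m <- sweep_matrix(sw)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(rownames(m), c("0.2", "1"))
  long_val <- sw$asynchrony_ms[sw$D == 0.2 & sw$tau_s == 0.1]
  expect_equal(m["0.2", "0.1"], round(long_val), ignore_attr = TRUE)
})

test_that("grid search recovers an on-grid parameter set from its own curve", {
  ioi <- c(1000, 2000, 3000)
  sim <- run_experiment1(profiles = "nonmusician", feedback = "on",
                         ioi_ms = ioi, cycles = 15)
  line <- lm(mean_asynchrony_ms ~ ioi_ms, data = sim)
  target <- list(slope = unname(coef(line)[2]),
                 intercept = unname(coef(line)[1]))
  fit <- fit_parameters(target, ioi_ms = ioi,
                        D_grid = c(0.05, 0.36), tau_grid = c(0.1, 0.222),
                        A_grid = -0.5, cycles = 15)
  expect_equal(fit$best_D, 0.36)
  expect_equal(fit$best_tau, 0.222)
  expect_equal(fit$best_A, -0.5)

  # the same grid point wins when the target line is perturbed slightly
  target2 <- list(slope = target$slope * 1.02, intercept = target$intercept + 0.5)
  fit2 <- fit_parameters(target2, ioi_ms = ioi,
                         D_grid = c(0.05, 0.36), tau_grid = c(0.1, 0.222),
                         A_grid = -0.5, cycles = 15)
  expect_equal(glance(fit2)[, c("best_D", "best_tau", "best_A")],
               glance(fit)[, c("best_D", "best_tau", "best_A")])
})

test_that("the fit objective is reproduced by an independent brute-force loop", {
  ioi <- c(1000, 2000)
  target <- list(slope = -0.02, intercept = -5)
  fit <- fit_parameters(target, ioi_ms = ioi, D_grid = c(0.05, 0.36),
                        tau_grid = 0.222, A_grid = -0.5, cycles = 12)
  for (r in seq_len(nrow(fit$grid))) {
    D <- fit$grid$D[r]
    sse <- 0
    for (ioi_i in ioi) {
      f <- 1000 / ioi_i
      p <- oscillator_params(f = f, D = D, tau = 0.222, A = -0.5)
      g <- quick_asynchrony(p, drive_on(fs = f), duration = 12 * ioi_i / 1000)
      y <- target$intercept + target$slope * ioi_i
      sse <- sse + (g$mean_asynchrony_ms - y)^2
    }
    expect_equal(fit$grid$objective[r], sse)
  }
})

test_that("degenerate fit inputs raise configuration errors", {
  expect_error(fit_parameters(list(slope = 0, intercept = 0),
                              D_grid = numeric(0), tau_grid = 0.2),
               "empty search grid")
  expect_error(fit_parameters(list(slope = 0), D_grid = 0.1, tau_grid = 0.2),
               "intercept")
})

test_that("phase-locked drive classifies as a fixed point from every start", {
  p <- oscillator_params(f = 1, D = 0, tau = 0, A = 0)
  cl <- classify_attractor(p, drive_off(), cycles = 15, last_cycles = 5)
  expect_equal(cl$verdict, "fixed_point")
  # all terminal phases coincide pairwise
  ph <- cl$terminal_phase
  expect_lt(max(abs(Arg(exp(1i * (outer(ph, ph, "-")))))), 1e-2)
})

test_that("a mode-locked cell classifies as a limit cycle", {
  p <- oscillator_params(f = 1, D = 1, tau = 0.3, A = 1)
  cl <- suppressWarnings(classify_attractor(p, drive_on(), cycles = 30))
  expect_equal(cl$verdict, "limit_cycle")
  expect_true(any(cl$looping))
})

test_that("classification is invariant to rotating the initial-phase grid", {
  p <- oscillator_params(f = 1, D = 0.3, tau = 0.2, A = -0.5)
  base <- seq(0, 2 * pi, length.out = 9)[-9]
  v1 <- classify_attractor(p, drive_on(), init_phases = base, cycles = 15,
                           last_cycles = 5)
  v2 <- classify_attractor(p, drive_on(), init_phases = base + 0.7,
                           cycles = 15, last_cycles = 5)
  expect_equal(v1$verdict, v2$verdict)
})
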