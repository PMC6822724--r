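#' Asynchrony over a (D, tau) grid
#'
#' Integrates the oscillator for every combination of delayed-feedback
#' amplitude `D` and delay `tau`, at a fixed input coefficient `A` and
#' frequency `f`, and records the steady-state asynchrony in ms. Cells
#' where no steady state is reached (mode-locking) or where the
#' integration fails are flagged `failed` and carry no asynchrony value.
#' With `A = 0` the oscillator is driven by the bare sinusoid; otherwise
#' by the normalised combination of sinusoid and own activity.
#'
#' @param A Input coefficient (0 means sinusoid-only drive).
#' @param f Oscillator and stimulus frequency in Hz.
#' @param D_grid Values of `D` (default 0 to 1 in steps of 0.05).
#' @param tau_grid Values of `tau` in seconds (default 27 points on
#'   0 to 0.5 s, placing 0.222 on the grid).
#' @param cycles Stimulus cycles per cell (default 20).
#' @param dt Integration step in seconds.
#' @return A `sappa_sweep` tibble with columns `A`, `f_hz`, `D`, `tau_s`,
#'   `asynchrony_ms`, `failed`.
#' @seealso [sweep_matrix()] for the D-by-tau matrix layout.
#' @examples
#' \donttest{
#' sw <- sweep_asynchrony(A = 0, D_grid = c(0, 1), tau_grid = c(0.05, 0.2))
#' }
#' @export
sweep_asynchrony <- function(A = -0.5, f = 1,
                             D_grid = seq(0, 1, by = 0.05),
                             tau_grid = seq(0, 0.5, length.out = 27),
                             cycles = 20, dt = 1e-3) {
  if (length(D_grid) == 0L || length(tau_grid) == 0L) {
    abort("`D_grid` and `tau_grid` must be non-empty.")
  }
  grid <- tidyr::expand_grid(D = D_grid, tau_s = tau_grid)
  fb <- if (A == 0) "off" else "constant_self"
  rows <- purrr::pmap(grid, function(D, tau_s) {
    params <- oscillator_params(f = f, D = D, tau = tau_s, A = A)
    spec <- stimulus_spec("sinusoid", fs = f, feedback_mode = fb)
    res <- tryCatch({
      traj <- sappa_integrate(params, spec, duration = cycles / f, dt = dt)
      glance(measure_asynchrony(traj))
    }, error = function(e) NULL)
    if (is.null(res) || !res$synchronized) {
      tibble(D = D, tau_s = tau_s, asynchrony_ms = NA_real_, failed = TRUE)
    } else {
      tibble(D = D, tau_s = tau_s, asynchrony_ms = res$mean_asynchrony_ms,
             failed = FALSE)
    }
  })
  out <- bind_rows(rows)
  out <- tibble(A = A, f_hz = f, out)
  attr(out, "config") <- list(A = A, f = f, D_grid = D_grid,
                              tau_grid = tau_grid, cycles = cycles, dt = dt)
  class(out) <- c("sappa_sweep", class(out))
  out
}

#' Matrix layout of a sweep
#'
#' Reshapes a [sweep_asynchrony()] result into a D-by-tau matrix of
#' asynchronies, rounded to integer ms (failed cells are `NA`).
#'
#' @param sweep A `sappa_sweep` tibble.
#' @return A numeric matrix with `D` values as row names and `tau` values
#'   (seconds) as column names.
#' @export
sweep_matrix <- function(sweep) {
  stopifnot(inherits(sweep, "sappa_sweep"))
  wide <- tidyr::pivot_wider(
    mutate(sweep, asynchrony_ms = round(.data$asynchrony_ms)),
    id_cols = "D", names_from = "tau_s", values_from = "asynchrony_ms"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$D
  m
}

#' Grid-search fit of D, tau, A to a target anticipation line
#'
#' Simulates the asynchrony-versus-IOI curve for every parameter
#' combination on the supplied grids and minimises the sum of squared
#' deviations from the target regression line
#' `asynchrony_ms = intercept_ms + slope * ioi_ms`. Ties are broken by the
#' smallest `D`, then the smallest `tau`, then the `A` closest to 0.
#' Combinations with any unsynchronized IOI are excluded.
#'
#' @param target A list (or named vector) with `slope` (ms of asynchrony
#'   per ms of IOI) and `intercept` (ms), e.g. a regression line fitted to
#'   behavioural data.
#' @param ioi_ms IOIs (ms) at which the curve is evaluated.
#' @param D_grid,tau_grid,A_grid Search grids.
#' @param cycles Stimulus cycles per run.
#' @param dt Integration step in seconds.
#' @return A `sappa_fit` with `best_D`, `best_tau`, `best_A`, `objective`
#'   and the full `grid` of objective values.
#' @export
fit_parameters <- function(target, ioi_ms = seq(1000, 3500, by = 250),
                           D_grid, tau_grid, A_grid = -0.5,
                           cycles = 20, dt = 1e-3) {
  if (length(D_grid) == 0L || length(tau_grid) == 0L || length(A_grid) == 0L) {
    abort("configuration error: empty search grid.")
  }
  target <- as.list(target)
  if (is.null(target$slope) || is.null(target$intercept)) {
    abort("`target` must supply `slope` and `intercept`.")
  }
  y <- target$intercept + target$slope * ioi_ms
  grid <- tidyr::expand_grid(D = D_grid, tau = tau_grid, A = A_grid)
  obj <- purrr::pmap_dbl(grid, function(D, tau, A) {
    sims <- vapply(ioi_ms, function(ioi) {
      f <- 1000 / ioi
      params <- oscillator_params(f = f, D = D, tau = tau, A = A)
      fb <- if (A == 0) "off" else "constant_self"
      spec <- stimulus_spec("sinusoid", fs = f, feedback_mode = fb)
      res <- tryCatch({
        traj <- sappa_integrate(params, spec, duration = cycles * ioi / 1000,
                                dt = dt)
        g <- glance(measure_asynchrony(traj))
        if (g$synchronized) g$mean_asynchrony_ms else NA_real_
      }, error = function(e) NA_real_)
      res
    }, numeric(1))
    if (anyNA(sims)) Inf else sum((sims - y)^2)
  })
  grid$objective <- obj
  if (all(!is.finite(obj))) abort("no fit: every grid combination failed to synchronize.")
  ranked <- arrange(grid, .data$objective, .data$D, .data$tau, abs(.data$A))
  best <- ranked[1, ]
  structure(
    list(best_D = best$D, best_tau = best$tau, best_A = best$A,
         objective = best$objective, grid = grid,
         target = target, ioi_ms = ioi_ms),
    class = "sappa_fit"
  )
}

#' @export
print.sappa_fit <- function(x, ...) {
  cat(sprintf("<sappa_fit> best D = %g, tau = %g s, A = %g (SSE = %.4g)\n",
              x$best_D, x$best_tau, x$best_A, x$objective))
  invisible(x)
}

#' Classify the attractor of the driven oscillator
#'
#' Integrates the oscillator from several initial phases and inspects the
#' relative phase between the oscillator and the stimulus carrier. When
#' every run settles (relative-phase excursion over the last `last_cycles`
#' cycles below `loop_tol`) and all terminal phases coincide within
#' `point_tol`, the attractor is a fixed point of the relative phase
#' (phase locking). When the relative phase keeps traversing a loop the
#' verdict is a limit cycle (mode locking). Mixed settled/looping runs are
#' reported as `limit_cycle` with a multistability warning.
#'
#' @param params An [oscillator_params()].
#' @param spec A [stimulus_spec()] with a periodic carrier.
#' @param init_phases Initial phases in radians (at least 8, spanning the
#'   circle).
#' @param cycles Stimulus cycles to integrate per initial phase.
#' @param last_cycles Window (in cycles) over which settling is judged.
#' @param point_tol Pairwise terminal-phase tolerance in radians.
#' @param loop_tol Relative-phase excursion threshold in radians.
#' @param dt Integration step in seconds.
#' @return A list with `verdict` (`"fixed_point"` or `"limit_cycle"`),
#'   `terminal_phase` (radians per initial phase), and `looping` flags.
#' @export
classify_attractor <- function(params, spec,
                               init_phases = seq(0, 2 * pi, length.out = 9L)[-9L],
                               cycles = 30, last_cycles = 10,
                               point_tol = 1e-2, loop_tol = 0.1, dt = 1e-3) {
  stopifnot(is_oscillator_params(params), inherits(spec, "stimulus_spec"))
  if (length(init_phases) < 8L) abort("supply at least 8 initial phases.")
  fs <- spec$fs
  runs <- lapply(init_phases, function(ph) {
    traj <- sappa_integrate(params, spec, duration = cycles / fs, dt = dt,
                            init_phase = ph)
    z <- complex(real = traj$re_z, imaginary = traj$im_z)
    rel <- Arg(z * exp(-1i * 2 * pi * fs * traj$time_s))
    win <- traj$time_s >= (cycles - last_cycles) / fs
    relw <- rel[win]
    # unwrap within the window to measure total excursion
    un <- cumsum(c(relw[1], Arg(exp(1i * diff(relw)))))
    list(excursion = max(un) - min(un), terminal = relw[length(relw)])
  })
  excursion <- vapply(runs, `[[`, numeric(1), "excursion")
  terminal <- vapply(runs, `[[`, numeric(1), "terminal")
  looping <- excursion > loop_tol
  if (any(looping)) {
    if (!all(looping)) {
      rlang::warn("mixed verdicts across initial conditions: possible multistability.")
    }
    verdict <- "limit_cycle"
  } else {
    pairwise <- outer(terminal, terminal, function(a, b) abs(Arg(exp(1i * (a - b)))))
    verdict <- if (max(pairwise) <= point_tol) "fixed_point" else "limit_cycle"
    if (verdict == "limit_cycle") {
      rlang::warn("settled runs ended at distinct phases: possible multistability.")
    }
  }
  list(verdict = verdict, terminal_phase = terminal, looping = looping,
       excursion = excursion)
}
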