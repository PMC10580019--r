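#' Measurement model for the tumour-volume feedback
#'
#' The controller sees \eqn{\bar x(t) = x(t) + A \sin(\omega t)}, optionally
#' sampled every `sample_period` days and held constant between measurements
#' (zero-order hold). The reference noisy scenario uses amplitude
#' A = 30 mm^3 and angular frequency 0.1 rad per time unit, applied with t in
#' days; the sampled scenario measures every 3 days. The default is
#' noise-free continuous feedback.
#'
#' @param noise_amplitude sinusoid amplitude A, mm^3; non-negative.
#' @param noise_frequency angular frequency omega, rad per day.
#' @param sample_period days between tumour-volume measurements, or `NULL`
#'   for continuous feedback; first measurement at t = 0.
#' @return Object of class `"measurement_spec"`.
#' @export
measurement_spec <- function(noise_amplitude = 0, noise_frequency = 0,
                             sample_period = NULL) {
  if (!is.numeric(noise_amplitude) || length(noise_amplitude) != 1L ||
      !is.finite(noise_amplitude) || noise_amplitude < 0) {
    stop("'noise_amplitude' must be a single non-negative number (mm^3)", call. = FALSE)
  }
  if (!is.numeric(noise_frequency) || length(noise_frequency) != 1L ||
      !is.finite(noise_frequency)) {
    stop("'noise_frequency' must be a single finite number (rad/day)", call. = FALSE)
  }
  if (!is.null(sample_period)) {
    if (!is.numeric(sample_period) || length(sample_period) != 1L ||
        !is.finite(sample_period) || sample_period <= 0) {
      stop("'sample_period' must be a single positive number of days (or NULL)",
           call. = FALSE)
    }
  }
  structure(list(noise_amplitude = noise_amplitude,
                 noise_frequency = noise_frequency,
                 sample_period = sample_period),
            class = "measurement_spec")
}

#' Plant-parameter perturbation
#'
#' Signed fractional deviations of the true plant from the nominal rates:
#' `delta_a = 0.5` means the true proliferation rate is 50\% above nominal.
#' Applied by [perturb_params()]; perturbed rates must stay positive, so each
#' delta must exceed -1.
#'
#' @param delta_a,delta_b,delta_c signed fractions.
#' @return Object of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(delta_a = 0, delta_b = 0, delta_c = 0) {
  d <- c(delta_a, delta_b, delta_c)
  if (!is.numeric(d) || length(d) != 3L || any(!is.finite(d))) {
    stop("perturbation fractions must be finite numbers", call. = FALSE)
  }
  structure(list(delta_a = delta_a, delta_b = delta_b, delta_c = delta_c),
            class = "perturbation_spec")
}

#' Apply a fractional perturbation to model rates
#'
#' @param nominal a [tumour_model()].
#' @param spec a [perturbation_spec()].
#' @return A [tumour_model()] with rates
#'   \eqn{(a(1+\delta_a), b(1+\delta_b), c(1+\delta_c))}; an error if any
#'   perturbed rate is non-positive.
#' @export
perturb_params <- function(nominal, spec) {
  stopifnot(inherits(nominal, "tumour_model"), inherits(spec, "perturbation_spec"))
  a <- nominal$a * (1 + spec$delta_a)
  b <- nominal$b * (1 + spec$delta_b)
  c <- nominal$c * (1 + spec$delta_c)
  if (a <= 0 || b <= 0 || c <= 0) {
    stop(sprintf(
      "perturbation (%g, %g, %g) drives a model rate non-positive (a=%.4g, b=%.4g, c=%.4g)",
      spec$delta_a, spec$delta_b, spec$delta_c, a, b, c), call. = FALSE)
  }
  tumour_model(a = a, b = b, c = c)
}

#' One tumour-volume measurement
#'
#' Returns the measurement the controller would use at time `t`: the noisy
#' value \eqn{x + A\sin(\omega t)}, or, under sampled feedback, the held
#' value unless `t` falls on a sampling instant (multiples of the sample
#' period, starting at t = 0), in which case a fresh noisy sample is taken.
#'
#' @param t time, days.
#' @param x_true true tumour volume at `t`, mm^3.
#' @param spec a [measurement_spec()].
#' @param held_value most recent sample, mm^3; required when holding and `t`
#'   is not a sampling instant.
#' @return measured tumour volume, mm^3 (may be negative; not clamped).
#' @export
make_measurement <- function(t, x_true, spec, held_value = NULL) {
  stopifnot(inherits(spec, "measurement_spec"))
  fresh <- x_true + spec$noise_amplitude * sin(spec$noise_frequency * t)
  if (is.null(spec$sample_period)) {
    return(fresh)
  }
  on_sample <- abs(t / spec$sample_period - round(t / spec$sample_period)) < 1e-9
  if (on_sample) {
    fresh
  } else {
    if (is.null(held_value)) {
      stop("'held_value' required between sampling instants", call. = FALSE)
    }
    held_value
  }
}

#' Simulation configuration
#'
#' Horizon, initial state, output grid and integrator tolerances for the
#' closed-loop run. The defaults reproduce the reference scenario: a
#' 10^4 mm^3 tumour, no drug on board, 100 days, output every 0.1 day.
#'
#' With the default controller the initial commanded dose is about
#' 7.4e5 mg/kg/day and the inhibitor level traverses several decades within
#' 1e-3 day, so the integrator defaults are stiff-safe: adaptive `lsoda`
#' with `rtol = atol = 1e-8` and the initial step capped at 1e-6 day.
#'
#' @param t_end horizon, days (> 0).
#' @param x0 initial tumour volume, mm^3 (>= 0).
#' @param y0 initial inhibitor level, mg/kg (>= 0).
#' @param dt output grid spacing, days.
#' @param rtol,atol relative/absolute integrator tolerances.
#' @param hini initial integrator step cap, days.
#' @param seed reserved for future stochastic scenarios; unused by the
#'   deterministic reference scenarios.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(t_end = 100, x0 = 1e4, y0 = 0, dt = 0.1,
                       rtol = 1e-8, atol = 1e-8, hini = 1e-6, seed = NULL) {
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (!is.numeric(x0) || x0 < 0) stop("'x0' must be non-negative", call. = FALSE)
  if (!is.numeric(y0) || y0 < 0) stop("'y0' must be non-negative", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0 || dt > t_end) {
    stop("'dt' must be positive and at most 't_end'", call. = FALSE)
  }
  if (!is.numeric(rtol) || rtol <= 0 || !is.numeric(atol) || atol <= 0) {
    stop("integrator tolerances must be positive", call. = FALSE)
  }
  if (!is.numeric(hini) || hini <= 0) stop("'hini' must be positive", call. = FALSE)
  structure(list(t_end = t_end, x0 = x0, y0 = y0, dt = dt,
                 rtol = rtol, atol = atol, hini = hini, seed = seed),
            class = "sim_config")
}

# Integrate the closed loop over [t0, t1] with either continuous feedback
# (u recomputed from the instantaneous noisy measurement inside the RHS) or a
# frozen injection rate (zero-order hold). Returns the deSolve matrix.
integrate_segment <- function(state, t0, t1, times, plant, controller, meas,
                              sim, u_held = NULL) {
  nom <- controller$nominal
  ck <- nom$c * controller$k
  if (is.null(u_held)) {
    rhs <- function(t, s, p) {
      xm <- s[1L] + meas$noise_amplitude * sin(meas$noise_frequency * t)
      u <- ck + nom$b * xm * xm
      list(c(plant$a * s[1L] - plant$b * s[1L] * s[2L],
             -plant$c * s[2L] + u))
    }
  } else {
    rhs <- function(t, s, p) {
      list(c(plant$a * s[1L] - plant$b * s[1L] * s[2L],
             -plant$c * s[2L] + u_held))
    }
  }
  out <- deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = sim$rtol, atol = sim$atol,
                      hini = sim$hini, maxsteps = 100000L)
  if (nrow(out) < length(times) || any(!is.finite(out[, c("x", "y")]))) {
    stop(sprintf(
      "integrator failed on [%.4g, %.4g] (step-size collapse or non-finite state); last state x=%.4g y=%.4g",
      t0, t1, out[nrow(out), "x"], out[nrow(out), "y"]), call. = FALSE)
  }
  out
}

#' Simulate the closed-loop therapy
#'
#' Integrates the tumour/inhibitor plant under the backstepping law
#' \eqn{u = \bar c k + \bar b \bar x^2}, where the measurement \eqn{\bar x}
#' may carry sinusoidal noise and may be sampled-and-held. The plant rates
#' may differ from the controller's nominal rates (robustness runs); pass a
#' perturbed [tumour_model()] as `plant`.
#'
#' Sampled runs are integrated piecewise between measurement updates so the
#' discontinuity in `u` always lands on an integrator restart, and the
#' injection rate recorded in the trajectory is the one actually applied
#' (held value included). Negative noisy measurements are passed through
#' unchanged; the law squares them.
#'
#' @param plant true-plant [tumour_model()].
#' @param controller a [backstepping_controller()].
#' @param sim a [sim_config()].
#' @param measurement a [measurement_spec()].
#'
#' @return Object of class `"therapy_sim"`: list with
#' \describe{
#'   \item{trajectory}{data.frame `t, x, y, u, e, x_measured` (days, mm^3,
#'     mg/kg, mg/kg/day, `e = y - k` mg/kg, mm^3).}
#'   \item{plant, controller, sim, measurement}{the inputs.}
#'   \item{solver}{method and tolerances used, number of segments.}
#' }
#' @examples
#' run <- simulate_therapy(sim = sim_config(t_end = 20))
#' summary(run)
#' @export
simulate_therapy <- function(plant = tumour_model(),
                             controller = backstepping_controller(),
                             sim = sim_config(),
                             measurement = measurement_spec()) {
  stopifnot(inherits(plant, "tumour_model"),
            inherits(controller, "bs_controller"),
            inherits(sim, "sim_config"),
            inherits(measurement, "measurement_spec"))
  nom <- controller$nominal
  ck <- nom$c * controller$k
  grid <- seq(0, sim$t_end, by = sim$dt)
  if (grid[length(grid)] < sim$t_end) grid <- c(grid, sim$t_end)
  state <- c(x = sim$x0, y = sim$y0)

  if (is.null(measurement$sample_period)) {
    out <- integrate_segment(state, 0, sim$t_end, grid, plant, controller,
                             measurement, sim)
    xm <- out[, "x"] + measurement$noise_amplitude *
      sin(measurement$noise_frequency * out[, "time"])
    traj <- data.frame(t = out[, "time"], x = out[, "x"], y = out[, "y"],
                       u = ck + nom$b * xm^2, e = out[, "y"] - controller$k,
                       x_measured = xm)
    n_seg <- 1L
  } else {
    period <- measurement$sample_period
    breaks <- unique(c(seq(0, sim$t_end, by = period), sim$t_end))
    pieces <- vector("list", length(breaks) - 1L)
    for (j in seq_len(length(breaks) - 1L)) {
      t0 <- breaks[j]; t1 <- breaks[j + 1L]
      held <- make_measurement(t0, unname(state[["x"]]), measurement)
      u_held <- ck + nom$b * held^2
      # keep grid points strictly inside the window; values within 1e-9 of a
      # breakpoint would duplicate it (floating grid arithmetic)
      times <- sort(unique(c(t0, grid[grid > t0 + 1e-9 & grid < t1 - 1e-9], t1)))
      out <- integrate_segment(state, t0, t1, times, plant, controller,
                               measurement, sim, u_held = u_held)
      state <- c(x = unname(out[nrow(out), "x"]), y = unname(out[nrow(out), "y"]))
      piece <- data.frame(t = out[, "time"], x = out[, "x"], y = out[, "y"],
                          u = u_held, e = out[, "y"] - controller$k,
                          x_measured = held)
      if (j > 1L) piece <- piece[-1L, , drop = FALSE]  # endpoint shared with previous piece
      pieces[[j]] <- piece
    }
    traj <- do.call(rbind, pieces)
    rownames(traj) <- NULL
    n_seg <- length(pieces)
  }

  res <- structure(list(trajectory = traj, plant = plant,
                        controller = controller, sim = sim,
                        measurement = measurement,
                        solver = list(method = "lsoda", rtol = sim$rtol,
                                      atol = sim$atol, hini = sim$hini,
                                      segments = n_seg)),
                   class = "therapy_sim")
  check_trajectory_invariants(res)
  res
}

# Positivity of the applied input and non-negativity of the states, up to
# solver tolerance; violations beyond tolerance are reported, not silently
# accepted.
check_trajectory_invariants <- function(run) {
  traj <- run$trajectory
  floor_u <- steady_state_injection(run$controller) - 1e-9
  if (min(traj$u) < floor_u) {
    warning(sprintf("input positivity violated: min u = %.6g < c*k = %.6g",
                    min(traj$u), floor_u + 1e-9), call. = FALSE)
  }
  tol <- 100 * run$sim$atol
  if (min(traj$x) < -tol || min(traj$y) < -tol) {
    warning(sprintf("state non-negativity violated beyond tolerance: min x = %.3g, min y = %.3g",
                    min(traj$x), min(traj$y)), call. = FALSE)
  }
  invisible(run)
}

#' @export
print.therapy_sim <- function(x, ...) {
  traj <- x$trajectory
  n <- nrow(traj)
  cat("Closed-loop anti-angiogenic therapy simulation\n")
  cat(sprintf("  horizon %g days, %d samples; x0 = %g mm^3, y0 = %g mg/kg, k = %g\n",
              x$sim$t_end, n, x$sim$x0, x$sim$y0, x$controller$k))
  if (x$measurement$noise_amplitude > 0) {
    cat(sprintf("  measurement noise: %g mm^3 at %g rad/day\n",
                x$measurement$noise_amplitude, x$measurement$noise_frequency))
  }
  if (!is.null(x$measurement$sample_period)) {
    cat(sprintf("  sampled feedback, zero-order hold every %g days\n",
                x$measurement$sample_period))
  }
  cat(sprintf("  terminal: x = %.4g mm^3, y = %.4f mg/kg, u = %.4f mg/kg/day\n",
              traj$x[n], traj$y[n], traj$u[n]))
  invisible(x)
}

#' @export
summary.therapy_sim <- function(object, ...) {
  m <- run_metrics(object)
  d <- gain_margin_quiet(object$controller, object$plant)
  out <- list(run = object, metrics = m, d = d)
  class(out) <- "summary.therapy_sim"
  out
}

#' @export
print.summary.therapy_sim <- function(x, ...) {
  print(x$run)
  cat(sprintf("  true-plant decay rate d = b*k - a = %.4g 1/day (%s)\n",
              x$d, if (x$d > 0) "gain condition holds" else "STABILITY CONDITION VIOLATED"))
  print(x$metrics)
  invisible(x)
}

# gain_margin without the warning, for display paths
gain_margin_quiet <- function(controller, plant) {
  plant$b * controller$k - plant$a
}

#' @export
coef.therapy_sim <- function(object, ...) {
  p <- object$plant; nom <- object$controller$nominal
  c(a = p$a, b = p$b, c = p$c,
    a_nominal = nom$a, b_nominal = nom$b, c_nominal = nom$c,
    k = object$controller$k,
    d = p$b * object$controller$k - p$a,
    u_steady = steady_state_injection(object$controller))
}

#' @export
as.data.frame.therapy_sim <- function(x, ...) x$trajectory

#' Plot a closed-loop run
#'
#' Three stacked panels: tumour volume (log scale once positive), inhibitor
#' level with the set-point k, and applied injection rate (log scale).
#'
#' @param x a `therapy_sim`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.therapy_sim <- function(x, ...) {
  traj <- x$trajectory
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 1.5, 1))
  on.exit(graphics::par(op))
  pos <- pmax(traj$x, x$sim$atol)
  graphics::plot(traj$t, pos, type = "l", log = "y", xlab = "time (days)",
                 ylab = expression(x ~ (mm^3)), main = "tumour volume", ...)
  graphics::plot(traj$t, traj$y, type = "l", xlab = "time (days)",
                 ylab = "y (mg/kg)", main = "inhibitor level", ...)
  graphics::abline(h = x$controller$k, lty = 2)
  graphics::plot(traj$t, traj$u, type = "l", log = "y", xlab = "time (days)",
                 ylab = "u (mg/kg/day)", main = "injection rate", ...)
  graphics::abline(h = steady_state_injection(x$controller), lty = 2)
  invisible(x)
}
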