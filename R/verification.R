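#' Lyapunov function of the tracking errors
#'
#' \eqn{V = \tfrac12 x^2 + \tfrac12 e^2}, where \eqn{x} is the tumour volume
#' and \eqn{e = y - k} the inhibitor tracking error. Vectorised.
#'
#' @param x tumour volume, mm^3.
#' @param e inhibitor tracking error, mg/kg.
#' @return V (non-negative).
#' @export
lyapunov_value <- function(x, e) 0.5 * x^2 + 0.5 * e^2

#' Analytic Lyapunov decay rate along the closed loop
#'
#' On the nominal closed loop the cross terms \eqn{\pm b x^2 e} cancel and
#' \eqn{\dot V = -d x^2 - c e^2} exactly, with \eqn{d = b k - a}. Evaluated
#' analytically at trajectory samples (no finite differencing, which would be
#' noisy on the stiff boundary layer).
#'
#' @param x tumour volume, mm^3.
#' @param e tracking error, mg/kg.
#' @param d net tumour decay rate, 1/day.
#' @param c clearance rate, 1/day.
#' @return dV/dt.
#' @seealso [lyapunov_rate_direct()] for the un-simplified expansion used as
#'   a cross-check of the cancellation.
#' @export
lyapunov_rate <- function(x, e, d, c) -d * x^2 - c * e^2

#' Direct expansion of the Lyapunov rate
#'
#' Computes \eqn{\dot V = x\dot x + e\dot e} from the closed-loop error
#' dynamics \eqn{\dot x = -d x - b x e}, \eqn{\dot e = -c e + b x^2} without
#' simplification. Algebraically identical to [lyapunov_rate()] (the
#' \eqn{b x^2 e} terms cancel); kept as an independent route for tests.
#'
#' @inheritParams lyapunov_rate
#' @param b inhibition efficacy, kg/mg/day.
#' @return dV/dt.
#' @export
lyapunov_rate_direct <- function(x, e, d, c, b) {
  x * (-d * x - b * x * e) + e * (-c * e + b * x^2)
}

#' Check the exponential-decay envelopes along a nominal run
#'
#' Certifies, sample by sample, the Lyapunov envelope
#' \eqn{V(t) \le V(0) e^{-\gamma t}} and the state envelopes
#' \eqn{|x(t)|, |e(t)| \le \beta e^{-\gamma t/2}}, with
#' \eqn{\gamma = 2\min\{d, c\}} and \eqn{\beta = \sqrt{x(0)^2 + e(0)^2}}.
#' Meant for nominal (unperturbed, continuous, noise-free) runs, where the
#' theory guarantees the envelopes; perturbed runs are covered by
#' [check_bibo()].
#'
#' Envelope comparisons allow a relative slack of `tol` plus an absolute
#' floor of `abs_floor` for near-zero states.
#'
#' @param run a [simulate_therapy()] result, or a data.frame with columns
#'   `t, x, e`.
#' @param constants [stability_constants()]; computed from `run` when
#'   missing.
#' @param tol relative envelope tolerance.
#' @param abs_floor absolute tolerance floor.
#' @return Object of class `"lyapunov_report"`: list with the `V` and
#'   analytic `Vdot` series, the three envelope margin series (bound minus
#'   value), per-sample pass flags, worst margins and overall `pass`.
#' @export
check_decay <- function(run, constants = NULL, tol = 1e-6, abs_floor = 1e-12) {
  traj <- if (inherits(run, "therapy_sim")) run$trajectory else run
  stopifnot(all(c("t", "x", "e") %in% names(traj)))
  if (is.null(constants)) {
    if (!inherits(run, "therapy_sim")) {
      stop("'constants' must be supplied for a bare trajectory", call. = FALSE)
    }
    constants <- stability_constants(run$controller, run$plant,
                                     traj$x[1L], traj$e[1L] + run$controller$k)
  }
  stopifnot(inherits(constants, "stability_constants"))
  g <- constants$gamma
  V <- lyapunov_value(traj$x, traj$e)
  cr <- if (inherits(run, "therapy_sim")) run$plant$c else NA_real_
  Vdot <- if (is.finite(cr)) lyapunov_rate(traj$x, traj$e, constants$d, cr) else NULL
  v_bound <- V[1L] * exp(-g * traj$t) * (1 + tol) + abs_floor
  s_bound <- constants$beta * exp(-g * traj$t / 2) * (1 + tol) + abs_floor
  ok_v <- V <= v_bound
  ok_x <- abs(traj$x) <= s_bound
  ok_e <- abs(traj$e) <= s_bound
  worst <- c(V = min(v_bound - V),
             x = min(s_bound - abs(traj$x)),
             e = min(s_bound - abs(traj$e)))
  structure(list(t = traj$t, V = V, Vdot = Vdot,
                 pass_by_sample = ok_v & ok_x & ok_e,
                 worst_margin = worst,
                 n_violations = sum(!(ok_v & ok_x & ok_e)),
                 constants = constants,
                 pass = all(ok_v) && all(ok_x) && all(ok_e)),
            class = "lyapunov_report")
}

#' @export
print.lyapunov_report <- function(x, ...) {
  cat("Exponential-decay envelope check\n")
  cat(sprintf("  gamma = %.6g 1/day, beta = %.6g; %d samples\n",
              x$constants$gamma, x$constants$beta, length(x$t)))
  cat(sprintf("  result: %s (%d violating samples)\n",
              if (x$pass) "PASS" else "FAIL", x$n_violations))
  cat(sprintf("  worst margins  V: %.3g  |x|: %.3g  |e|: %.3g\n",
              x$worst_margin["V"], x$worst_margin["x"], x$worst_margin["e"]))
  invisible(x)
}

#' Parametric-mismatch disturbance along a run
#'
#' When the true plant differs from the controller's nominal rates, the
#' error dynamics see the lumped disturbance
#' \eqn{u_d(t) = -(c - \bar c)\, e(t) + (b - \bar b)\, x(t)^2.}
#' Returns the series and its sup norm \eqn{\delta_d}, the tightest
#' checkable disturbance bound for that trajectory (the theory assumes only
#' that some bound exists on the region of operation).
#'
#' @param run a [simulate_therapy()] result.
#' @param plant true-plant [tumour_model()]; defaults to the run's plant.
#' @param nominal nominal [tumour_model()]; defaults to the run's controller
#'   nominal.
#' @return list `(t, u_d, delta_d)`.
#' @export
disturbance_signal <- function(run, plant = run$plant,
                               nominal = run$controller$nominal) {
  stopifnot(inherits(run, "therapy_sim"),
            inherits(plant, "tumour_model"), inherits(nominal, "tumour_model"))
  traj <- run$trajectory
  u_d <- -(plant$c - nominal$c) * traj$e + (plant$b - nominal$b) * traj$x^2
  list(t = traj$t, u_d = u_d, delta_d = max(abs(u_d)))
}

#' Robust (BIBO) trajectory envelope
#'
#' Bound on the error-state norm \eqn{\|X(t)\|}, \eqn{X = (x, e)}, for a
#' perturbed closed loop subject to a disturbance bounded by
#' \eqn{\delta_d}:
#' \deqn{\|X(t)\| \le \|X(0)\| e^{-\bar\gamma t}
#'   + \frac{\delta_d}{\bar\gamma}\left(1 - e^{-\bar\gamma t}\right),}
#' with \eqn{\bar\gamma = \min\{d, \bar c\}}. The disturbance gain
#' \eqn{\delta_d/\bar\gamma} is the one the comparison-lemma derivation
#' yields for \eqn{W = \sqrt V}; see the methods vignette for why a gain
#' tightened by 1/2 is not an invariant of these trajectories.
#'
#' @param t time, days; vectorised.
#' @param X0_norm \eqn{\|X(0)\|}.
#' @param gamma_bar robust decay rate, 1/day; must be positive.
#' @param delta_d disturbance sup-norm; non-negative.
#' @return envelope values at `t`.
#' @export
bibo_envelope <- function(t, X0_norm, gamma_bar, delta_d) {
  if (!is.numeric(gamma_bar) || length(gamma_bar) != 1L || gamma_bar <= 0) {
    stop("'gamma_bar' must be positive: the envelope exists only when the gain condition holds for the true plant",
         call. = FALSE)
  }
  if (delta_d < 0) stop("'delta_d' must be non-negative", call. = FALSE)
  decay <- exp(-gamma_bar * t)
  X0_norm * decay + delta_d / gamma_bar * (1 - decay)
}

#' Check the BIBO envelope along a perturbed run
#'
#' Computes the empirical disturbance bound \eqn{\delta_d} via
#' [disturbance_signal()], the envelope via [bibo_envelope()] with
#' \eqn{\bar\gamma = \min\{d, \bar c\}} (true-plant \eqn{d}, nominal
#' clearance), and asserts \eqn{\|X(t)\|} stays below it at every sample.
#'
#' @param run a [simulate_therapy()] result whose true plant satisfies the
#'   gain condition.
#' @param tol relative slack on the envelope.
#' @return list: `pass`, `max_ratio` (sup of \eqn{\|X\|}/envelope),
#'   `delta_d`, `gamma_bar`, `X0_norm`, plus the `t`, `X_norm` and
#'   `envelope` series.
#' @export
check_bibo <- function(run, tol = 1e-6) {
  stopifnot(inherits(run, "therapy_sim"))
  traj <- run$trajectory
  d <- run$plant$b * run$controller$k - run$plant$a
  if (d <= 0) {
    stop("gain condition fails for the true plant (d <= 0); no BIBO envelope applies",
         call. = FALSE)
  }
  gb <- min(d, run$controller$nominal$c)
  ds <- disturbance_signal(run)
  Xn <- sqrt(traj$x^2 + traj$e^2)
  env <- bibo_envelope(traj$t, Xn[1L], gb, ds$delta_d)
  ratio <- Xn / env
  list(pass = all(Xn <= env * (1 + tol)),
       max_ratio = max(ratio),
       delta_d = ds$delta_d, gamma_bar = gb, X0_norm = Xn[1L],
       t = traj$t, X_norm = Xn, envelope = env)
}

#' Scalar metrics of a closed-loop run
#'
#' \describe{
#'   \item{overshoot}{\eqn{\max_t x(t)/x(0) - 1} (0 when `x0 = 0`). The
#'     transient rise of the tumour before the drug takes hold.}
#'   \item{t_below_1pct}{first time x falls below 1\% of x(0), days
#'     (`NA` if never).}
#'   \item{steady_x, steady_y, steady_u}{means over the final 10\% of the
#'     horizon, with flatness flags `flat_*` ((max - min) below 1\% of the
#'     mean magnitude, or below the solver atol for near-zero signals).}
#'   \item{decay_rate}{log-linear fit of x over the post-peak segment
#'     (samples with x above the atol floor), 1/day; `NA` when fewer than
#'     two usable samples.}
#' }
#'
#' @param run a [simulate_therapy()] result, or a data.frame with columns
#'   `t, x, y, u`.
#' @param atol absolute floor separating "zero" signals from real ones;
#'   taken from the run when available.
#' @return Object of class `"run_metrics"` (a list).
#' @export
run_metrics <- function(run, atol = NULL) {
  traj <- if (inherits(run, "therapy_sim")) run$trajectory else run
  stopifnot(all(c("t", "x", "y", "u") %in% names(traj)))
  if (nrow(traj) < 10L) {
    stop("trajectory too short for metrics (need >= 10 samples)", call. = FALSE)
  }
  if (is.null(atol)) {
    atol <- if (inherits(run, "therapy_sim")) run$sim$atol else 1e-8
  }
  t <- traj$t; x <- traj$x
  x0 <- x[1L]
  overshoot <- if (x0 > 0) max(x) / x0 - 1 else 0
  t_below <- if (x0 > 0) {
    idx <- which(x < 0.01 * x0)
    if (length(idx)) t[min(idx)] else NA_real_
  } else NA_real_

  tail_idx <- which(t >= t[length(t)] - 0.1 * (t[length(t)] - t[1L]))
  steady <- function(v) {
    m <- mean(v[tail_idx])
    spread <- diff(range(v[tail_idx]))
    list(mean = m, flat = spread < max(0.01 * abs(m), atol))
  }
  sx <- steady(traj$x); sy <- steady(traj$y); su <- steady(traj$u)

  ipk <- which.max(x)
  post <- seq(ipk, length(x))
  post <- post[x[post] > 10 * atol]
  decay <- if (length(post) >= 2L) {
    fit <- stats::lm(log(x[post]) ~ t[post])
    -unname(stats::coef(fit)[2L])
  } else NA_real_

  structure(list(overshoot = overshoot, t_below_1pct = t_below,
                 steady_x = sx$mean, flat_x = sx$flat,
                 steady_y = sy$mean, flat_y = sy$flat,
                 steady_u = su$mean, flat_u = su$flat,
                 decay_rate = decay),
            class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  cat("Run metrics\n")
  cat(sprintf("  overshoot           : %.4g (max x / x0 - 1)\n", x$overshoot))
  cat(sprintf("  time to 1%% of x0    : %s days\n",
              if (is.na(x$t_below_1pct)) "never" else format(x$t_below_1pct)))
  cat(sprintf("  steady x            : %.4g mm^3%s\n", x$steady_x,
              if (x$flat_x) "" else "  [not settled]"))
  cat(sprintf("  steady y            : %.4f mg/kg%s\n", x$steady_y,
              if (x$flat_y) "" else "  [not settled]"))
  cat(sprintf("  steady u            : %.4f mg/kg/day%s\n", x$steady_u,
              if (x$flat_u) "" else "  [not settled]"))
  cat(sprintf("  fitted x decay rate : %.4g 1/day\n", x$decay_rate))
  invisible(x)
}
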