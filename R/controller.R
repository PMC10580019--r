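#' Positive-input backstepping controller
#'
#' Builds the tumour-volume-feedback control law
#' \deqn{u(t) = \bar c\, k + \bar b\, \bar x(t)^2,}
#' where \eqn{\bar x} is the measured tumour volume, \eqn{k} is the control
#' gain and \eqn{(\bar a, \bar b, \bar c)} are the *nominal* model rates the
#' controller was designed with (the true plant may differ). The gain doubles
#' as the desired inhibitor level \eqn{y^\ast = k}: once \eqn{y \to k}, the
#' net tumour decay rate is \eqn{d = b k - a > 0}.
#'
#' Construction enforces the gain condition \eqn{k > \bar a / \bar b} against
#' the nominal rates: the controller cannot know the true plant, and the
#' condition is what makes the design-time decay rate
#' \eqn{\bar d = \bar b k - \bar a} positive. Whether the *true* plant also
#' satisfies it is a separate diagnostic, [gain_margin()], used by the
#' robustness sweep.
#'
#' Both terms of the law are non-negative for any real measurement (the
#' second is a square), so the commanded injection rate is always at least
#' \eqn{\bar c k > 0}: input positivity is structural, not clipped.
#'
#' @param k control gain, mg/kg; also the inhibitor set-point
#'   \eqn{y^\ast}. Must exceed \eqn{\bar a/\bar b} (about 36.49 mg/kg at the
#'   default rates). Default 60, the reference-scenario gain.
#' @param nominal a [tumour_model()] with the nominal rates
#'   \eqn{(\bar a, \bar b, \bar c)}.
#' @return An object of class `"bs_controller"`: list with `k` and `nominal`.
#' @seealso [control_input()], [gain_margin()], [stability_constants()]
#' @examples
#' ctrl <- backstepping_controller(k = 60)
#' control_input(0, ctrl)        # floor dose c*k ~ 10.664 mg/kg/day
#' @export
backstepping_controller <- function(k = 60, nominal = tumour_model()) {
  stopifnot(inherits(nominal, "tumour_model"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("control gain 'k' must be a single positive finite number", call. = FALSE)
  }
  kmin <- nominal$a / nominal$b
  if (k <= kmin) {
    stop(sprintf(
      "gain condition violated: k = %g must exceed a/b = %.6g (nominal rates); the net tumour decay rate b*k - a would not be positive",
      k, kmin), call. = FALSE)
  }
  structure(list(k = k, nominal = nominal), class = "bs_controller")
}

#' @export
print.bs_controller <- function(x, ...) {
  cat("Backstepping tumour-therapy controller  u = c*k + b*x_measured^2\n")
  cat(sprintf("  gain k (= desired inhibitor level y*) : %g mg/kg\n", x$k))
  cat(sprintf("  nominal rates  a = %.6g, b = %.6g, c = %.6g\n",
              x$nominal$a, x$nominal$b, x$nominal$c))
  cat(sprintf("  design decay rate  b*k - a = %.6g 1/day\n",
              x$nominal$b * x$k - x$nominal$a))
  cat(sprintf("  steady-state injection  c*k = %.6g mg/kg/day\n",
              x$nominal$c * x$k))
  invisible(x)
}

#' Desired inhibitor level
#'
#' The backstepping set-point for the inhibitor serum level is the constant
#' \eqn{y^\ast = k}; it does not depend on time or on the state.
#'
#' @param controller a [backstepping_controller()].
#' @return y*, mg/kg.
#' @export
desired_inhibitor <- function(controller) {
  stopifnot(inherits(controller, "bs_controller"))
  controller$k
}

#' Control law: injection rate from a tumour-volume measurement
#'
#' Evaluates \eqn{u = \bar c k + \bar b \bar x^2} for measured tumour volume
#' `x_measured`. The measurement may be negative (noise-corrupted); the law
#' squares it. The result is always at least \eqn{\bar c k > 0}.
#'
#' @param x_measured measured tumour volume, mm^3; finite, vectorised.
#' @param controller a [backstepping_controller()].
#' @return injection rate u, mg/kg/day.
#' @export
control_input <- function(x_measured, controller) {
  stopifnot(inherits(controller, "bs_controller"))
  if (!is.numeric(x_measured) || any(!is.finite(x_measured))) {
    stop("'x_measured' must be finite (got non-finite measurement)", call. = FALSE)
  }
  nom <- controller$nominal
  nom$c * controller$k + nom$b * x_measured^2
}

#' Gain margin against a (possibly perturbed) true plant
#'
#' The net tumour decay rate the closed loop achieves on a given plant is
#' \eqn{d = b k - a} with the plant's *true* rates. A non-positive `d` means
#' the gain condition fails for that plant: the tumour is not driven to zero.
#' Used by the robustness sweep, which deliberately explores violations, so a
#' bad margin is flagged (attribute `stable`, plus a warning) rather than
#' raised as an error.
#'
#' @param controller a [backstepping_controller()].
#' @param plant a [tumour_model()] with the true rates.
#' @return `d` (1/day) with logical attribute `"stable"` (`d > 0`).
#' @export
gain_margin <- function(controller, plant) {
  stopifnot(inherits(controller, "bs_controller"), inherits(plant, "tumour_model"))
  d <- plant$b * controller$k - plant$a
  if (d <= 0) {
    warning(sprintf(
      "stability condition violated for this plant: d = b*k - a = %.6g <= 0", d),
      call. = FALSE)
  }
  structure(d, stable = d > 0)
}

#' Exponential-stability constants of the closed loop
#'
#' For a plant satisfying the gain condition, the Lyapunov analysis of the
#' closed loop yields
#' \describe{
#'   \item{`d`}{net tumour decay rate \eqn{b k - a}, 1/day (true plant).}
#'   \item{`gamma`}{decay rate of \eqn{V = \tfrac12 x^2 + \tfrac12 e^2}:
#'     \eqn{\gamma = 2\min\{d, c\}}, 1/day.}
#'   \item{`gamma_bar`}{robust decay rate used by the disturbance envelope:
#'     \eqn{\bar\gamma = \min\{d, \bar c\}}, 1/day (nominal clearance).}
#'   \item{`beta`}{state-envelope amplitude
#'     \eqn{\beta = \sqrt{x(0)^2 + e(0)^2}} with \eqn{e = y - k}. The theory
#'     only requires \eqn{\beta \ge} this value; the tightest valid choice is
#'     used.}
#' }
#' The state envelopes are \eqn{|x(t)|, |e(t)| \le \beta e^{-\gamma t / 2}}.
#'
#' @param controller a [backstepping_controller()].
#' @param plant true-plant [tumour_model()].
#' @param x0 initial tumour volume, mm^3.
#' @param y0 initial inhibitor level, mg/kg.
#' @return Object of class `"stability_constants"`:
#'   list `(d, gamma, gamma_bar, beta)`.
#' @export
stability_constants <- function(controller, plant, x0, y0) {
  stopifnot(inherits(controller, "bs_controller"), inherits(plant, "tumour_model"))
  d <- plant$b * controller$k - plant$a
  if (d <= 0) {
    stop(sprintf("gain condition fails for this plant (d = %.6g <= 0); no exponential-stability constants exist", d),
         call. = FALSE)
  }
  e0 <- y0 - controller$k
  structure(list(d = d,
                 gamma = 2 * min(d, plant$c),
                 gamma_bar = min(d, controller$nominal$c),
                 beta = sqrt(x0^2 + e0^2)),
            class = "stability_constants")
}

#' @export
print.stability_constants <- function(x, ...) {
  cat("Closed-loop stability constants\n")
  cat(sprintf("  d         = %.6g 1/day   (net tumour decay rate)\n", x$d))
  cat(sprintf("  gamma     = %.6g 1/day   (Lyapunov decay, 2*min(d, c))\n", x$gamma))
  cat(sprintf("  gamma_bar = %.6g 1/day   (robust decay, min(d, c_nom))\n", x$gamma_bar))
  cat(sprintf("  beta      = %.6g        (envelope amplitude)\n", x$beta))
  invisible(x)
}

#' Steady-state injection rate
#'
#' Once the tumour is eradicated (\eqn{x \to 0}) the law settles at the
#' maintenance dose \eqn{u_\infty = k \bar c}, independent of
#' \eqn{\bar a, \bar b} and of any plant perturbation in \eqn{a} or \eqn{b}.
#'
#' @param controller a [backstepping_controller()].
#' @return u at steady state, mg/kg/day.
#' @export
steady_state_injection <- function(controller) {
  stopifnot(inherits(controller, "bs_controller"))
  controller$k * controller$nominal$c
}
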