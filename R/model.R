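#' Tumour-growth model parameters
#'
#' Container for the rate constants of the two-state tumour/inhibitor model
#' \deqn{\dot x = a x - b x y, \qquad \dot y = -c y + u(t),}
#' where \eqn{x} is the tumour volume (mm\eqn{^3}), \eqn{y} the inhibitor
#' serum level (mg/kg) and \eqn{u} the inhibitor injection rate (mg/kg/day).
#' The tumour proliferates at rate \eqn{a}, is suppressed by the inhibitor
#' with efficacy \eqn{b}, and the drug is cleared from serum with first-order
#' rate \eqn{c = \ln 2 / t_{1/2}}.
#'
#' The defaults are the mouse-model rates used throughout the reference
#' scenarios: \eqn{a = 0.27}/day, \eqn{b = 0.0074} kg/mg/day and a drug
#' half-life of 3.9 days (\eqn{c = \ln 2 / 3.9}/day, kept at full floating
#' precision, never as a rounded literal). A second instance of this type
#' holds the *nominal* rates a controller believes in; see
#' [backstepping_controller()].
#'
#' @param a tumour proliferation rate, 1/day; must be positive.
#' @param b inhibition efficacy, kg/mg/day; must be positive.
#' @param c drug clearance rate, 1/day; must be positive.
#'
#' @return An object of class `"tumour_model"`: a list with elements
#'   `a`, `b`, `c`.
#' @seealso [vector_field()], [perturb_params()], [backstepping_controller()]
#' @examples
#' tumour_model()                    # reference rates
#' tumour_model(a = 0.54)           # doubled proliferation rate
#' @export
tumour_model <- function(a = 0.27, b = 0.0074, c = log(2) / 3.9) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model parameter '", nm, "' must be a single positive finite number, got ",
           deparse(v), call. = FALSE)
    }
  }
  structure(list(a = a, b = b, c = c), class = "tumour_model")
}

#' @export
print.tumour_model <- function(x, ...) {
  cat("Tumour-growth model parameters\n")
  cat(sprintf("  a (proliferation) : %.6g 1/day\n", x$a))
  cat(sprintf("  b (inhibition)    : %.6g kg/mg/day\n", x$b))
  cat(sprintf("  c (clearance)     : %.6g 1/day  (half-life %.4g days)\n",
              x$c, log(2) / x$c))
  invisible(x)
}

#' Right-hand side of the tumour/inhibitor model
#'
#' Evaluates \eqn{(\dot x, \dot y) = (a x - b x y,\; -c y + u)} at one state.
#' This is the open-loop vector field: the injection rate `u` is supplied by
#' the caller (the closed-loop simulator substitutes the control law).
#'
#' @param state numeric of length 2, `c(x, y)`: tumour volume (mm^3) and
#'   inhibitor level (mg/kg). Must be finite.
#' @param params a [tumour_model()].
#' @param u injection rate, mg/kg/day; must be finite and non-negative.
#'
#' @return Named numeric `c(dx = ..., dy = ...)`, units mm^3/day and
#'   mg/kg/day.
#' @examples
#' vector_field(c(x = 1e4, y = 0), tumour_model(), u = 0)  # (2700, 0)
#' @export
vector_field <- function(state, params, u) {
  stopifnot(inherits(params, "tumour_model"))
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state))) {
    stop("'state' must be a finite numeric vector c(x, y); got ",
         paste(format(state), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0) {
    stop("injection rate 'u' must be a single finite non-negative number; got ",
         deparse(u), call. = FALSE)
  }
  x <- state[[1L]]
  y <- state[[2L]]
  c(dx = params$a * x - params$b * x * y, dy = -params$c * y + u)
}

#' Inhibitor level under a constant injection rate (closed form)
#'
#' Solves \eqn{\dot y = -c y + u} for constant `u`:
#' \eqn{y(t) = u/c + (y_0 - u/c) e^{-c t}}. Used as an independent oracle for
#' the numerical integrator.
#'
#' @param t time since treatment start, days; non-negative, vectorised.
#' @param y0 initial inhibitor level, mg/kg.
#' @param u constant injection rate, mg/kg/day.
#' @param params a [tumour_model()]; only `c` is used.
#' @return y(t), mg/kg.
#' @export
inhibitor_closed_form <- function(t, y0, u, params) {
  stopifnot(inherits(params, "tumour_model"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be non-negative (days)", call. = FALSE)
  }
  yss <- u / params$c
  yss + (y0 - yss) * exp(-params$c * t)
}

#' Tumour volume under a constant inhibitor level (closed form)
#'
#' Solves \eqn{\dot x = (a - b y) x} for constant `y_const`:
#' \eqn{x(t) = x_0 e^{(a - b\,y_\mathrm{const}) t}}. At
#' `y_const = a/b` the net growth rate is zero; above it the tumour decays
#' exponentially. Oracle for the numerical integrator.
#'
#' @param t time, days; non-negative, vectorised.
#' @param x0 initial tumour volume, mm^3.
#' @param y_const held inhibitor level, mg/kg.
#' @param params a [tumour_model()].
#' @return x(t), mm^3.
#' @export
tumour_constant_inhibitor <- function(t, x0, y_const, params) {
  stopifnot(inherits(params, "tumour_model"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be non-negative (days)", call. = FALSE)
  }
  x0 * exp((params$a - params$b * y_const) * t)
}

#' Jacobian of the virtual-input extended system
#'
#' Earlier positivity-preserving designs extend the plant with the bilinear
#' input dynamic \eqn{\dot u = -v u}, where \eqn{v} is a virtual input; the
#' real input then stays positive for any \eqn{v}. This function linearises
#' the extended system \eqn{(\dot x, \dot y, \dot u) =
#' (a x - b x y,\; -c y + u,\; -v u)} with respect to the states
#' \eqn{(x, y, u)} at a frozen point, treating \eqn{v} as a parameter.
#'
#' The Jacobian is upper-triangular,
#' \deqn{J = \begin{pmatrix} a - b y & -b x & 0 \\ 0 & -c & 1 \\
#'   0 & 0 & -v \end{pmatrix},}
#' so its eigenvalues are the diagonal entries \eqn{\{a - b y, -c, -v\}}
#' exactly: the tumour-row eigenvalue is the net growth rate at the frozen
#' inhibitor level, and the inhibitor-row eigenvalue is always the negated
#' clearance rate \eqn{-c}.
#'
#' @param params a [tumour_model()].
#' @param x,y,u frozen state: tumour volume (mm^3), inhibitor level (mg/kg),
#'   injection rate (mg/kg/day). `u` does not enter the Jacobian but is kept
#'   for completeness of the linearisation point.
#' @param v frozen virtual input, 1/day.
#'
#' @return A list of class `"extended_jacobian"`:
#' \describe{
#'   \item{jacobian}{3 x 3 matrix with dimnames `(x, y, u)`.}
#'   \item{eigenvalues}{diagonal eigenvalues sorted by decreasing real part.}
#'   \item{eigen_by_state}{named `c(x=, y=, u=)` eigenvalues in state
#'     (diagonal) order: the `y` entry is \eqn{-c}.}
#' }
#' @examples
#' ej <- extended_jacobian(tumour_model(), x = 1e-3, y = 1e-3, v = 0)
#' round(ej$eigen_by_state["y"], 4)   # -0.1777
#' @export
extended_jacobian <- function(params, x, y, v, u = 0) {
  stopifnot(inherits(params, "tumour_model"))
  pt <- c(x, y, v, u)
  if (!is.numeric(pt) || length(pt) != 4L || any(!is.finite(pt))) {
    stop("extended-system point (x, y, v, u) must be finite", call. = FALSE)
  }
  J <- matrix(c(params$a - params$b * y, -params$b * x, 0,
                0,                      -params$c,      1,
                0,                       0,            -v),
              nrow = 3L, byrow = TRUE,
              dimnames = list(c("x", "y", "u"), c("x", "y", "u")))
  lam <- diag(J)
  structure(list(jacobian = J,
                 eigenvalues = lam[order(-lam)],
                 eigen_by_state = lam),
            class = "extended_jacobian")
}

#' @export
print.extended_jacobian <- function(x, ...) {
  cat("Extended-system (x, y, u) Jacobian, u' = -v u:\n")
  print(x$jacobian)
  cat("Eigenvalues (descending):", paste(format(x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}
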