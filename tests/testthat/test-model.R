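test_that("vector field matches the model equations at hand-checked states", {
  p <- ref_plant
  # untreated reference tumour grows at a*x
  expect_equal(unname(vector_field(c(1e4, 0), p, u = 0)), c(0.27 * 1e4, 0))
  # (x = 0, y = k, u = c*k) is an equilibrium by construction
  eq <- vector_field(c(0, 60), p, u = 60 * p$c)
  expect_equal(unname(eq), c(0, 0))
  # at y = a/b the net tumour growth rate vanishes
  vf <- vector_field(c(100, p$a / p$b), p, u = 0)
  expect_equal(unname(vf), c(0, -p$c * p$a / p$b))
})

test_that("vector field rejects bad inputs with a diagnostic", {
  expect_error(vector_field(c(NaN, 0), ref_plant, u = 0), "finite")
  expect_error(vector_field(c(1, Inf), ref_plant, u = 0), "finite")
  expect_error(vector_field(c(1, 1), ref_plant, u = -1), "non-negative")
  expect_error(tumour_model(a = -0.1), "positive")
  expect_error(tumour_model(b = 0), "positive")
})

test_that("inhibitor closed form: initial condition, fixed point, limit", {
  p <- ref_plant
  expect_equal(inhibitor_closed_form(0, y0 = 12, u = 3, p), 12)
  # u = c*y0 holds the level constant
  tt <- seq(0, 40, by = 5)
  expect_equal(inhibitor_closed_form(tt, y0 = 25, u = p$c * 25, p),
               rep(25, length(tt)))
  # from zero, constant u = 60*c settles at 60
  expect_equal(inhibitor_closed_form(500, y0 = 0, u = 60 * p$c, p),
               60, tolerance = 1e-12)
  expect_error(inhibitor_closed_form(-1, 0, 1, p), "non-negative")
})

test_that("tumour closed form: stasis at a/b, free growth, treated decay", {
  p <- ref_plant
  tt <- seq(0, 30, by = 3)
  expect_equal(tumour_constant_inhibitor(tt, x0 = 500, y_const = p$a / p$b, p),
               rep(500, length(tt)))
  expect_equal(tumour_constant_inhibitor(10, x0 = 7, y_const = 0, p),
               7 * exp(0.27 * 10))
  # held at the set-point y = 60 the tumour decays at d = b*k - a = 0.174
  expect_equal(tumour_constant_inhibitor(10, 1e4, 60, p), 1e4 * exp(-1.74))
  expect_equal(tumour_constant_inhibitor(10, 1e4, 60, p), 1755.204,
               tolerance = 1e-6)
  expect_error(tumour_constant_inhibitor(c(1, -2), 1, 1, p), "non-negative")
})

test_that("closed forms agree with numerical integration of the vector field", {
  p <- ref_plant
  tt <- seq(0, 50, by = 0.5)
  # hold y at y0 via u = c*y0 and start x anywhere: both closed forms at once
  y_hold <- 50
  rhs <- function(t, s, q) list(vector_field(s, p, u = p$c * y_hold))
  out <- deSolve::ode(c(x = 2000, y = y_hold), tt, rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(out[, "x"] - tumour_constant_inhibitor(tt, 2000, y_hold, p)) /
                  tumour_constant_inhibitor(tt, 2000, y_hold, p)), 1e-8)
  expect_lt(max(abs(out[, "y"] - y_hold) / y_hold), 1e-8)
  # relaxing inhibitor under constant input, from below the steady level
  rhs2 <- function(t, s, q) list(vector_field(s, p, u = 8))
  out2 <- deSolve::ode(c(x = 0, y = 5), tt, rhs2, NULL,
                       method = "lsoda", rtol = 1e-10, atol = 1e-10)
  cf <- inhibitor_closed_form(tt, 5, 8, p)
  expect_lt(max(abs(out2[, "y"] - cf) / cf), 1e-8)
})

test_that("extended Jacobian is upper-triangular with diagonal eigenvalues", {
  p <- ref_plant
  ej <- extended_jacobian(p, x = 1e-3, y = 1e-3, v = 0)
  J <- ej$jacobian
  expect_equal(J[lower.tri(J)], rep(0, 3))
  expect_identical(unname(ej$eigen_by_state), unname(diag(J)))
  # inhibitor-row eigenvalue is always the negated clearance rate
  expect_equal(unname(ej$eigen_by_state["y"]), -log(2) / 3.9)
  expect_equal(round(unname(ej$eigen_by_state["y"]), 4), -0.1777)
  # tumour-row eigenvalue a - b*y prints as 0.2699 when truncated, 0.2700 rounded
  expect_equal(floor(unname(ej$eigen_by_state["x"]) * 1e4) / 1e4, 0.2699)
  # special point: y = a/b, v = c
  ej2 <- extended_jacobian(p, x = 1, y = p$a / p$b, v = p$c)
  expect_equal(sort(unname(ej2$eigen_by_state)), sort(c(0, -p$c, -p$c)))
})

test_that("extended Jacobian eigenvalues match a dense eigensolver", {
  set.seed(42)
  for (i in 1:20) {
    p <- tumour_model(a = runif(1, 0.05, 1), b = runif(1, 1e-3, 1e-2),
                      c = runif(1, 0.05, 1))
    ej <- extended_jacobian(p, x = runif(1, 0, 1e4), y = runif(1, 0, 100),
                            v = runif(1, -1, 1))
    dense <- sort(Re(eigen(ej$jacobian, only.values = TRUE)$values),
                  decreasing = TRUE)
    expect_lt(max(abs(sort(unname(ej$eigen_by_state), decreasing = TRUE) - dense)),
              1e-12)
    # reported order is descending real part
    expect_identical(unname(ej$eigenvalues), sort(unname(ej$eigenvalues),
                                                  decreasing = TRUE))
  }
})
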