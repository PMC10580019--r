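test_that("measurement model: sinusoid, sampling instants, hold", {
  noisy <- measurement_spec(noise_amplitude = 30, noise_frequency = 0.1)
  expect_equal(make_measurement(0, 1234, noisy), 1234)          # sin 0 = 0
  expect_equal(make_measurement(pi / 0.2, 500, noisy), 530)     # sine peak
  held <- measurement_spec(sample_period = 3)
  expect_equal(make_measurement(3, 800, held), 800)             # fresh sample
  expect_equal(make_measurement(4, 999, held, held_value = 800), 800)
  expect_error(make_measurement(4, 999, held), "held_value")
  expect_error(measurement_spec(noise_amplitude = -1), "non-negative")
  expect_error(measurement_spec(sample_period = 0), "positive")
})

test_that("perturbation arithmetic and positivity guard", {
  nom <- ref_plant
  same <- perturb_params(nom, perturbation_spec())
  expect_equal(unclass(same), unclass(nom))
  expect_equal(perturb_params(nom, perturbation_spec(delta_a = 1))$a, 0.54)
  expect_equal(perturb_params(nom, perturbation_spec(delta_b = -0.1))$b, 0.00666)
  expect_error(perturb_params(nom, perturbation_spec(delta_c = -1)), "non-positive")
})

test_that("the x = 0 plane is invariant and y follows the first-order closed form", {
  run <- simulate_therapy(sim = sim_config(t_end = 50, x0 = 0, y0 = 0))
  traj <- run$trajectory
  expect_lte(max(abs(traj$x)), 1e-12)
  cf <- 60 * (1 - exp(-(log(2) / 3.9) * traj$t))
  expect_lt(max(abs(traj$y - cf) / pmax(cf, 1e-9)), 1e-8)
  # with no tumour the dose sits exactly at the maintenance level
  expect_equal(traj$u, rep(u_inf, nrow(traj)))
})

test_that("nominal run reaches the predicted limits", {
  traj <- nominal_run$trajectory
  n <- nrow(traj)
  expect_lt(traj$x[n], 1e-9 * 1e4)
  expect_equal(traj$y[n], 60, tolerance = 5e-3)
  expect_equal(traj$u[n], u_inf, tolerance = 5e-3)
  # states stay non-negative and input at or above the floor throughout
  expect_gte(min(traj$u), u_inf - 1e-9)
  expect_gte(min(traj$x), -1e-8)
  expect_gte(min(traj$y), -1e-8)
})

test_that("adaptive solution matches a fixed-step 4th-order oracle", {
  # independent route: classical RK4 at h = 1e-4 day over the first 2 days
  p <- ref_plant
  rhs <- function(t, s, q) {
    u <- u_inf + 0.0074 * s[1]^2
    list(c(p$a * s[1] - p$b * s[1] * s[2], -p$c * s[2] + u))
  }
  hh <- seq(0, 2, by = 1e-4)
  oracle <- deSolve::rk4(c(x = 1e4, y = 0), hh, rhs, NULL)
  keep <- seq(1, length(hh), by = 500)
  run <- simulate_therapy(sim = sim_config(t_end = 2, dt = 0.05))
  traj <- run$trajectory
  o_t <- hh[keep]
  idx <- match(round(o_t, 10), round(traj$t, 10))
  ok <- !is.na(idx)
  ox <- oracle[keep, "x"][ok]; oy <- oracle[keep, "y"][ok]
  sx <- traj$x[idx[ok]]; sy <- traj$y[idx[ok]]
  # x compared where it is resolvable above the absolute-tolerance floor
  res <- ox > 1e-3
  expect_lt(max(abs(sx[res] - ox[res]) / ox[res]), 1e-5)
  expect_lt(max(abs(sy - oy) / pmax(abs(oy), 1)), 1e-5)
})

test_that("output-grid refinement and tighter tolerances leave the answer unchanged", {
  # x0 = 100 keeps the terminal tumour volume well above the absolute
  # tolerance, where a relative comparison is meaningful
  base <- simulate_therapy(sim = sim_config(t_end = 30, x0 = 100, dt = 0.1))
  fine <- simulate_therapy(sim = sim_config(t_end = 30, x0 = 100, dt = 0.05,
                                            rtol = 1e-9, atol = 1e-9))
  nb <- nrow(base$trajectory); nf <- nrow(fine$trajectory)
  expect_lt(abs(base$trajectory$x[nb] - fine$trajectory$x[nf]) /
              abs(fine$trajectory$x[nf]), 1e-6)
  expect_lt(abs(base$trajectory$y[nb] - fine$trajectory$y[nf]) /
              abs(fine$trajectory$y[nf]), 1e-6)
})

test_that("sampled feedback holds the dose between 3-day measurements", {
  run <- simulate_therapy(sim = sim_config(t_end = 30),
                          measurement = measurement_spec(sample_period = 3))
  traj <- run$trajectory
  # within (3, 6) the measurement equals the t = 3 sample and u is constant
  x3 <- traj$x[traj$t == 3]
  in_win <- traj$t > 3 & traj$t < 6
  expect_true(all(traj$x_measured[in_win] == x3))
  expect_true(all(traj$u[in_win] == u_inf + 0.0074 * x3^2))
  # one distinct dose level per window
  expect_lte(length(unique(traj$u)), ceiling(30 / 3) + 1)
  expect_gte(min(traj$u), u_inf - 1e-9)
  expect_gte(min(traj$x), -1e-8)
})

test_that("noisy measurements pass through unclamped and keep the dose positive", {
  run <- simulate_therapy(
    sim = sim_config(t_end = 80, x0 = 0),
    measurement = measurement_spec(noise_amplitude = 30, noise_frequency = 0.1))
  traj <- run$trajectory
  expect_lt(min(traj$x_measured), 0)    # pure noise goes negative; not clamped
  expect_gte(min(traj$u), u_inf - 1e-9)
  expect_gte(min(traj$y), -1e-8)
})

test_that("with no tumour the inhibitor trajectory is blind to the plant's a", {
  cfg <- sim_config(t_end = 40, x0 = 0)
  r1 <- simulate_therapy(plant = tumour_model(a = 0.27), sim = cfg)
  r2 <- simulate_therapy(plant = tumour_model(a = 0.54), sim = cfg)
  expect_lt(max(abs(r1$trajectory$y - r2$trajectory$y)), 1e-12)
})

test_that("classed run object exposes the modelling-idiom surface", {
  expect_s3_class(nominal_run, "therapy_sim")
  cf <- coef(nominal_run)
  expect_equal(unname(cf["d"]), 0.174)
  expect_equal(unname(cf["u_steady"]), u_inf)
  df <- as.data.frame(nominal_run)
  expect_named(df, c("t", "x", "y", "u", "e", "x_measured"))
  expect_true(all(diff(df$t) > 0))
  expect_output(print(nominal_run), "terminal")
  expect_output(print(summary(nominal_run)), "gain condition holds")
})
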