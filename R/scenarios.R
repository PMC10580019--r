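#' Construct a named scenario
#'
#' A scenario bundles everything one closed-loop experiment needs: true
#' plant, controller, simulation grid, measurement model, an optional list of
#' plant perturbations (sweeps), and which verification checks to attach.
#'
#' @param name unique scenario name.
#' @param plant true-plant [tumour_model()].
#' @param controller a [backstepping_controller()].
#' @param sim a [sim_config()].
#' @param measurement a [measurement_spec()].
#' @param perturbations list of [perturbation_spec()] (empty for a single
#'   run).
#' @param checks character subset of `c("positivity", "decay", "bibo")`.
#' @return Object of class `"scenario"`.
#' @export
scenario <- function(name, plant = tumour_model(),
                     controller = backstepping_controller(),
                     sim = sim_config(), measurement = measurement_spec(),
                     perturbations = list(), checks = "positivity") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bad <- setdiff(checks, c("positivity", "decay", "bibo"))
  if (length(bad)) stop("unknown checks: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, plant = plant, controller = controller,
                 sim = sim, measurement = measurement,
                 perturbations = perturbations, checks = checks),
            class = "scenario")
}

# Sweep grid: each fraction in +-(0.1..1.0) applied to one rate at a time and
# jointly to all three. Grid points that would zero a rate (delta = -1) are
# kept in summaries as infeasible but never simulated.
sweep_grid <- function(deltas = seq(0.1, 1, by = 0.1)) {
  deltas <- sort(unique(c(deltas, -deltas)))
  rows <- list()
  for (par in c("a", "b", "c", "joint")) {
    for (dl in deltas) {
      spec <- switch(par,
        a = perturbation_spec(delta_a = dl),
        b = perturbation_spec(delta_b = dl),
        c = perturbation_spec(delta_c = dl),
        joint = perturbation_spec(dl, dl, dl))
      rows[[length(rows) + 1L]] <- list(parameter = par, delta = dl, spec = spec)
    }
  }
  rows
}

#' The reference scenarios
#'
#' Returns the four built-in experiments:
#' \describe{
#'   \item{nominal}{true plant equals nominal, 100 days, continuous
#'     noise-free feedback; positivity + exponential-decay checks.}
#'   \item{uncertainty_sweep}{the nominal run plus fractional perturbations
#'     of the true plant, 10\%--100\% in both signs, one rate at a time and
#'     all three jointly; positivity + BIBO checks on every stable grid
#'     point.}
#'   \item{noise}{sinusoidal measurement noise, amplitude 30 mm^3, angular
#'     frequency 0.1 rad/day; positivity.}
#'   \item{sampled}{tumour volume measured every 3 days, zero-order hold;
#'     positivity.}
#' }
#' All use the reference initial state (x0 = 1e4 mm^3, y0 = 0) and gain
#' k = 60.
#'
#' @return Named list of [scenario()] objects.
#' @export
builtin_scenarios <- function() {
  base_sim <- sim_config()
  list(
    nominal = scenario("nominal", checks = c("positivity", "decay")),
    uncertainty_sweep = scenario("uncertainty_sweep",
      perturbations = lapply(sweep_grid(), `[[`, "spec"),
      checks = c("positivity", "bibo")),
    noise = scenario("noise",
      measurement = measurement_spec(noise_amplitude = 30,
                                     noise_frequency = 0.1)),
    sampled = scenario("sampled",
      measurement = measurement_spec(sample_period = 3))
  )
}

#' Run the uncertainty sweep
#'
#' Simulates the closed loop for every grid point of the 10\%--100\%
#' perturbation sweep and summarises each run. Grid points whose true plant
#' violates the gain condition (`b*k - a <= 0`) are simulated and reported
#' with `stable = FALSE` rather than dropped; points whose perturbation
#' would zero a rate are reported with `feasible = FALSE` and skipped.
#'
#' @param controller a [backstepping_controller()].
#' @param sim a [sim_config()].
#' @param deltas positive perturbation fractions; both signs are applied.
#' @param keep_runs keep the full `therapy_sim` objects (memory-heavier).
#' @return list with `summary` (data.frame keyed by parameter, delta,
#'   feasible, stable, with min_u, bibo max ratio, steady u, terminal x) and,
#'   when `keep_runs`, the list `runs`.
#' @export
run_sweep <- function(controller = backstepping_controller(),
                      sim = sim_config(),
                      deltas = seq(0.1, 1, by = 0.1),
                      keep_runs = FALSE) {
  grid <- sweep_grid(deltas)
  nom <- controller$nominal
  rows <- vector("list", length(grid))
  runs <- if (keep_runs) vector("list", length(grid)) else NULL
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    feasible <- with(g$spec, all(c(1 + delta_a, 1 + delta_b, 1 + delta_c) > 0))
    row <- data.frame(parameter = g$parameter, delta = g$delta,
                      feasible = feasible, stable = NA, d = NA_real_,
                      min_u = NA_real_, delta_d = NA_real_,
                      bibo_max_ratio = NA_real_, bibo_pass = NA,
                      steady_u = NA_real_, terminal_x = NA_real_,
                      terminal_y = NA_real_)
    if (feasible) {
      plant <- perturb_params(nom, g$spec)
      d <- plant$b * controller$k - plant$a
      run <- simulate_therapy(plant, controller, sim)
      traj <- run$trajectory
      m <- run_metrics(run)
      row$stable <- d > 0
      row$d <- d
      row$min_u <- min(traj$u)
      row$steady_u <- m$steady_u
      row$terminal_x <- traj$x[nrow(traj)]
      row$terminal_y <- traj$y[nrow(traj)]
      if (d > 0) {
        bc <- check_bibo(run)
        row$delta_d <- bc$delta_d
        row$bibo_max_ratio <- bc$max_ratio
        row$bibo_pass <- bc$pass
      }
      if (keep_runs) runs[[i]] <- run
    }
    rows[[i]] <- row
  }
  out <- list(summary = do.call(rbind, rows))
  if (keep_runs) out$runs <- runs
  out
}

#' Write a trajectory as CSV
#'
#' Canonical export: a `#`-prefixed units comment, then the header
#' `t,x,y,u,e,x_measured`. Deterministic for identical runs (full `%.15g`
#' precision, fixed column order).
#'
#' @param run a [simulate_therapy()] result or its trajectory data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  traj <- if (inherits(run, "therapy_sim")) run$trajectory else run
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# t: day, x: mm3, y: mg/kg, u: mg/kg/day, e: mg/kg, x_measured: mm3", con)
  writeLines("t,x,y,u,e,x_measured", con)
  lines <- sprintf("%.15g,%.15g,%.15g,%.15g,%.15g,%.15g",
                   traj$t, traj$x, traj$y, traj$u, traj$e, traj$x_measured)
  writeLines(lines, con)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return data.frame `t, x, y, u, e, x_measured`.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Re-check a saved trajectory
#'
#' Re-validates a trajectory CSV without re-integrating: input positivity
#' (`u >= c*k`), consistency of the recorded injection rate with the control
#' law applied to the recorded measurement, and (optionally) the
#' exponential-decay envelopes.
#'
#' @param path trajectory CSV.
#' @param controller the [backstepping_controller()] that produced it.
#' @param plant true plant, for the decay constants; defaults to nominal.
#' @param decay also check the Lyapunov envelopes (nominal runs only).
#' @return list of check results; element `pass` aggregates them.
#' @export
verify_trajectory <- function(path, controller = backstepping_controller(),
                              plant = controller$nominal, decay = FALSE) {
  traj <- read_trajectory_csv(path)
  floor_u <- steady_state_injection(controller) - 1e-9
  pos <- min(traj$u) >= floor_u
  law <- max(abs(traj$u - control_input(traj$x_measured, controller))) <= 1e-6 * max(traj$u)
  out <- list(positivity = pos, law_consistent = law)
  if (decay) {
    const <- stability_constants(controller, plant, traj$x[1L],
                                 traj$e[1L] + controller$k)
    rep <- check_decay(traj, const)
    out$decay <- rep$pass
    out$decay_report <- rep
  }
  out$pass <- all(unlist(out[c("positivity", "law_consistent",
                               if (decay) "decay")]))
  out
}

#' Run a scenario and export its artifacts
#'
#' Runs one built-in (or custom) scenario end to end and writes its
#' canonical outputs to `outdir`: `trajectory.csv`, `metrics.json` (config
#' echo, metrics, verification results) and `report.txt`. A sweep scenario
#' writes one trajectory per feasible grid point
#' (`trajectory_<parameter>_<delta>.csv`) plus `summary.csv`.
#'
#' @param x a [scenario()] or the name of a built-in one.
#' @param outdir writable output directory (created if missing).
#' @return Invisibly, a list with the run(s), check results and written
#'   file paths; element `pass` reports overall verification outcome
#'   (unstable sweep points are reported, not failed).
#' @export
run_scenario <- function(x, outdir) {
  if (is.character(x)) {
    reg <- builtin_scenarios()
    if (!x %in% names(reg)) {
      stop("unknown scenario '", x, "'; built-ins: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    x <- reg[[x]]
  }
  stopifnot(inherits(x, "scenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- list(
    name = x$name,
    plant = unclass(x$plant), k = x$controller$k,
    nominal = unclass(x$controller$nominal),
    sim = unclass(x$sim)[c("t_end", "x0", "y0", "dt", "rtol", "atol", "hini")],
    measurement = list(noise_amplitude = x$measurement$noise_amplitude,
                       noise_frequency = x$measurement$noise_frequency,
                       sample_period = x$measurement$sample_period))

  if (length(x$perturbations)) {
    sw <- run_sweep(x$controller, x$sim, keep_runs = TRUE)
    files <- character(0)
    for (i in seq_len(nrow(sw$summary))) {
      if (!isTRUE(sw$summary$feasible[i])) next
      f <- file.path(outdir, sprintf("trajectory_%s_%+.1f.csv",
                                     sw$summary$parameter[i], sw$summary$delta[i]))
      write_trajectory_csv(sw$runs[[i]], f)
      files <- c(files, f)
    }
    sum_path <- file.path(outdir, "summary.csv")
    utils::write.csv(sw$summary, sum_path, row.names = FALSE)
    pass <- all(sw$summary$min_u[sw$summary$feasible] >=
                  steady_state_injection(x$controller) - 1e-9) &&
      all(sw$summary$bibo_pass[which(sw$summary$stable)])
    meta <- c(cfg_echo, list(summary = sw$summary, pass = pass))
    json_path <- file.path(outdir, "metrics.json")
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    report_path <- file.path(outdir, "report.txt")
    writeLines(c(sprintf("scenario: %s", x$name),
                 sprintf("grid points: %d (%d feasible, %d stable)",
                         nrow(sw$summary), sum(sw$summary$feasible),
                         sum(sw$summary$stable, na.rm = TRUE)),
                 sprintf("input positivity: %s", all(sw$summary$min_u[sw$summary$feasible] >=
                           steady_state_injection(x$controller) - 1e-9)),
                 sprintf("BIBO envelope (stable points): %s",
                         all(sw$summary$bibo_pass[which(sw$summary$stable)])),
                 sprintf("overall: %s", if (pass) "PASS" else "FAIL")),
               report_path)
    return(invisible(list(sweep = sw, pass = pass,
                          files = c(files, sum_path, json_path, report_path))))
  }

  run <- simulate_therapy(x$plant, x$controller, x$sim, x$measurement)
  traj <- run$trajectory
  metrics <- run_metrics(run)
  checks <- list()
  if ("positivity" %in% x$checks) {
    checks$positivity <- min(traj$u) >= steady_state_injection(x$controller) - 1e-9
  }
  if ("decay" %in% x$checks) {
    rep <- check_decay(run)
    checks$decay <- rep$pass
    checks$decay_worst_margin <- as.list(rep$worst_margin)
  }
  if ("bibo" %in% x$checks) {
    bc <- check_bibo(run)
    checks$bibo <- bc$pass
    checks$bibo_max_ratio <- bc$max_ratio
  }
  flags <- checks[intersect(names(checks), c("positivity", "decay", "bibo"))]
  pass <- all(unlist(flags))
  traj_path <- file.path(outdir, "trajectory.csv")
  write_trajectory_csv(run, traj_path)
  json_path <- file.path(outdir, "metrics.json")
  jsonlite::write_json(c(cfg_echo, list(metrics = unclass(metrics),
                                        checks = checks, pass = pass,
                                        solver = run$solver)),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null")
  report_path <- file.path(outdir, "report.txt")
  writeLines(c(sprintf("scenario: %s", x$name),
               utils::capture.output(print(summary(run))),
               sprintf("checks: %s",
                       paste(sprintf("%s=%s", names(flags), unlist(flags)),
                             collapse = " ")),
               sprintf("overall: %s", if (pass) "PASS" else "FAIL")),
             report_path)
  invisible(list(run = run, metrics = metrics, checks = checks, pass = pass,
                 files = c(traj_path, json_path, report_path)))
}

# Recognised flat config keys and where they land.
config_keys <- c("name", "a", "b", "c", "k",
                 "t_end", "x0", "y0", "dt", "rtol", "atol", "hini", "seed",
                 "noise_amplitude", "noise_frequency", "sample_period",
                 "delta_a", "delta_b", "delta_c", "checks")

#' Load a scenario from a flat key-value config file
#'
#' YAML file with flat keys mirroring the constructor arguments:
#' model rates `a, b, c` (nominal), gain `k`, simulation keys
#' `t_end, x0, y0, dt, rtol, atol, hini, seed`, measurement keys
#' `noise_amplitude, noise_frequency, sample_period`, perturbation keys
#' `delta_a, delta_b, delta_c`, plus `name` and `checks`. Every key is
#' optional; an empty file yields the nominal scenario. Unknown keys are
#' rejected with their names. All constructor validation applies (e.g. a
#' gain below a/b, or a negative noise amplitude, is rejected).
#'
#' @param path config file.
#' @return A [scenario()] whose plant is the nominal model perturbed by any
#'   `delta_*` keys.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a flat key-value mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; recognised keys: ", paste(config_keys, collapse = ", "), call. = FALSE)
  }
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  nominal <- tumour_model(a = pick("a", 0.27), b = pick("b", 0.0074),
                          c = pick("c", log(2) / 3.9))
  ctrl <- backstepping_controller(k = pick("k", 60), nominal = nominal)
  sim <- sim_config(t_end = pick("t_end", 100), x0 = pick("x0", 1e4),
                    y0 = pick("y0", 0), dt = pick("dt", 0.1),
                    rtol = pick("rtol", 1e-8), atol = pick("atol", 1e-8),
                    hini = pick("hini", 1e-6), seed = cfg$seed)
  meas <- measurement_spec(noise_amplitude = pick("noise_amplitude", 0),
                           noise_frequency = pick("noise_frequency", 0),
                           sample_period = cfg$sample_period)
  pert <- perturbation_spec(delta_a = pick("delta_a", 0),
                            delta_b = pick("delta_b", 0),
                            delta_c = pick("delta_c", 0))
  plant <- perturb_params(nominal, pert)
  scenario(name = pick("name", "config"), plant = plant, controller = ctrl,
           sim = sim, measurement = meas,
           checks = pick("checks", "positivity"))
}
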