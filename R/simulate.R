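## Scenario configuration and deterministic integration of the ODE system.

#' Cluster scenario labels
#'
#' The four subcellular cluster regimes: `NO_CLUSTER` (no spatial
#' organization), `SMALL` (single-enzyme PFKL clusters only), `MEDIUM`
#' (medium-sized multienzyme complexes, smaller clusters also present) and
#' `LARGE` (large multienzyme complexes in the presence of smaller clusters).
#'
#' @return Character vector of the four labels.
#' @export
scenario_labels <- function() c("NO_CLUSTER", "SMALL", "MEDIUM", "LARGE")

#' Apply a cluster scenario to a parameter set
#'
#' Zeroes the association/disassociation rates and catalytic-efficiency
#' factors of the cluster classes excluded by a scenario, leaving the input
#' untouched:
#' \describe{
#'   \item{NO_CLUSTER}{zero `k_as`, `k_mas`, `k_am`, `k_mam`, `k_al`,
#'     `k_mal` and all `c_i`, `e_i`}
#'   \item{SMALL}{zero `k_am`, `k_mam`, `k_al`, `k_mal` and all `c_i`,
#'     `e_i`; small-cluster rates kept}
#'   \item{MEDIUM}{zero `k_al`, `k_mal` and all `e_i`; `c_i` kept}
#'   \item{LARGE}{unchanged (the full model)}
#' }
#'
#' @param params A `glucosome_params`.
#' @param scenario One of [scenario_labels()].
#' @return A modified copy of `params`.
#' @export
apply_scenario <- function(params, scenario) {
  scenario <- match.arg(scenario, scenario_labels())
  p <- glucosome_parameters(values = unclass(params))
  ce <- c(medium_efficiency_names(), large_efficiency_names())
  zero <- switch(scenario,
    NO_CLUSTER = c("k_as", "k_mas", "k_am", "k_mam", "k_al", "k_mal", ce),
    SMALL      = c("k_am", "k_mam", "k_al", "k_mal", ce),
    MEDIUM     = c("k_al", "k_mal", large_efficiency_names()),
    LARGE      = character())
  p[zero] <- 0
  p
}

#' Simulate the glucose metabolic pathway
#'
#' Integrates the 19-variable ODE system from `initial` under the
#' scenario-adjusted parameters, on a uniform time grid over `[0, t_end]`.
#' The integrator is `deSolve::ode(method = "lsoda")` with tight tolerances
#' (the system is stiff in `E_M` through the 11th-power condensation term).
#' By default the compiled C right-hand side is used; `compiled = FALSE`
#' selects the pure-R route (identical model, used for cross-checks).
#'
#' Enzyme conservation is checked at every grid point; a warning is issued
#' if any total drifts by more than `1e-6` from its initial value.
#'
#' @param initial Initial `glucosome_state`. Default: the model's standard
#'   initial conditions.
#' @param params `glucosome_params` before scenario adjustment.
#' @param scenario One of [scenario_labels()].
#' @param t_end End time (non-dimensional), > 0. Default 10, the horizon at
#'   which all headline product readouts are quoted.
#' @param n_points Number of grid points including both endpoints, >= 2.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param compiled Use the compiled right-hand side (default) or the R one.
#' @return A `glucosome_trajectory`: list with `times` (length `n_points`),
#'   `states` (`n_points` x 19 matrix), `scenario`, `params` (the
#'   scenario-adjusted set actually integrated), `params_input`,
#'   `max_conservation_drift`.
#' @export
simulate_pathway <- function(initial = default_initial_state(),
                             params = default_parameters(),
                             scenario = "LARGE",
                             t_end = 10, n_points = 1001,
                             rtol = 1e-8, atol = 1e-10,
                             compiled = TRUE) {
  scenario <- match.arg(scenario, scenario_labels())
  stopifnot(t_end > 0, n_points >= 2)
  y0 <- setNames(as.numeric(initial[state_names()]), state_names())
  validate_state(y0)
  p_run <- apply_scenario(params, scenario)
  times <- seq(0, t_end, length.out = n_points)
  pv <- setNames(as.numeric(p_run), parameter_names())
  out <- if (compiled) {
    deSolve::ode(y0, times, func = "glucosim_derivs", parms = pv,
                 dllname = "glucosim", initfunc = "glucosim_initmod",
                 method = "lsoda", rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y0, times, rhs_r, pv, method = "lsoda",
                 rtol = rtol, atol = atol)
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0)
    stop("integrator failure (istate = ", istate, ") near t = ",
         signif(max(out[, "time"]), 6))
  if (nrow(out) < n_points)
    stop("integrator failure: trajectory truncated at t = ",
         signif(max(out[, "time"]), 6))
  states <- out[, state_names(), drop = FALSE]
  cons <- conservation_totals(states)
  drift <- max(abs(sweep(cons, 2, cons[1, ], "-")))
  if (drift > 1e-6)
    warning("enzyme conservation drift ", signif(drift, 3), " exceeds 1e-6")
  structure(list(times = times, states = states, scenario = scenario,
                 params = p_run, params_input = params,
                 max_conservation_drift = drift),
            class = "glucosome_trajectory")
}

#' @export
print.glucosome_trajectory <- function(x, ...) {
  cat("<glucosome_trajectory> scenario ", x$scenario, ", ",
      length(x$times), " points over t = [", min(x$times), ", ",
      max(x$times), "]\n", sep = "")
  fin <- x$states[nrow(x$states), c("P1", "P2", "P3")]
  cat("  products at t_end: P1 =", signif(fin[1], 4),
      " P2 =", signif(fin[2], 4), " P3 =", signif(fin[3], 4), "\n")
  cat("  max conservation drift:", signif(x$max_conservation_drift, 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.glucosome_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, scenario = x$scenario,
             check.names = FALSE)
}

#' Product levels at a grid time
#'
#' Reads the three product concentrations `(P1, P2, P3)` off a trajectory at
#' time `t`. `t` must hit a grid point exactly (up to floating-point grid
#' rounding); no interpolation is performed.
#'
#' @param traj A `glucosome_trajectory`.
#' @param t Time on the trajectory grid.
#' @return Named numeric vector `c(P1, P2, P3)`.
#' @export
product_levels_at <- function(traj, t) {
  stopifnot(inherits(traj, "glucosome_trajectory"))
  tol <- max(1e-9, 1e-9 * max(abs(traj$times)))
  i <- which(abs(traj$times - t) <= tol)
  if (length(i) != 1L)
    stop("t = ", t, " is not on the trajectory grid")
  traj$states[i, c("P1", "P2", "P3")]
}

#' One-parameter sweep envelopes
#'
#' Varies a single rate constant over a uniform grid from `lo` to `hi`
#' (direction preserved, so `lo > hi` sweeps downward), simulates each value
#' under each requested scenario -- scenario zeroing is applied after the
#' override, so sweeping a parameter the scenario zeroes yields a constant
#' envelope -- and records the per-time-point minimum and maximum of the
#' three products across the grid (the envelope), together with every
#' per-value product trajectory.
#'
#' @param name A parameter name from [parameter_names()].
#' @param lo,hi Sweep endpoints (inclusive).
#' @param n_values Number of grid values, >= 1.
#' @param scenarios Character vector of scenario labels.
#' @param t_end,n_points,params,initial Passed to [simulate_pathway()].
#' @param ... Further arguments to [simulate_pathway()].
#' @return A `sweep_envelope`: list with `parameter`, `values`, `times` and,
#'   per scenario, `min`/`max` (`n_points` x 3 matrices over P1..P3) and
#'   `products` (an `n_points` x 3 x `n_values` array).
#' @export
sweep_parameter <- function(name, lo, hi, n_values,
                            scenarios = scenario_labels(),
                            t_end = 10, n_points = 1001,
                            params = default_parameters(),
                            initial = default_initial_state(), ...) {
  if (!name %in% parameter_names())
    stop("unknown parameter: ", name)
  stopifnot(n_values >= 1)
  scenarios <- vapply(scenarios, match.arg, "", choices = scenario_labels())
  values <- seq(lo, hi, length.out = n_values)
  per_scenario <- lapply(setNames(scenarios, scenarios), function(sc) {
    prods <- array(NA_real_, dim = c(n_points, 3, length(values)),
                   dimnames = list(NULL, c("P1", "P2", "P3"), NULL))
    for (k in seq_along(values)) {
      p <- params
      p[name] <- values[k]
      tr <- simulate_pathway(initial, p, sc, t_end = t_end,
                             n_points = n_points, ...)
      prods[, , k] <- tr$states[, c("P1", "P2", "P3")]
    }
    list(min = apply(prods, c(1, 2), min),
         max = apply(prods, c(1, 2), max),
         products = prods)
  })
  structure(list(parameter = name, values = values,
                 times = seq(0, t_end, length.out = n_points),
                 scenarios = per_scenario),
            class = "sweep_envelope")
}

#' @export
print.sweep_envelope <- function(x, ...) {
  cat("<sweep_envelope> ", x$parameter, " over [",
      min(x$values), ", ", max(x$values), "] (", length(x$values),
      " values), scenarios: ", paste(names(x$scenarios), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
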