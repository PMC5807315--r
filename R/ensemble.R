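## Population-level ("ensemble") flux prediction: mix the four subcellular
## scenario product trajectories with measured fractions of cells per
## cluster class.

#' Construct a population distribution
#'
#' Fractions of cells per cluster scenario for one population/condition.
#' Fractions must be non-negative and sum to 1 (within 1e-6).
#'
#' @param label Condition name.
#' @param fractions Numeric vector of length 4 over
#'   `NO_CLUSTER, SMALL, MEDIUM, LARGE` (named or in that order).
#' @return A `population_distribution`.
#' @export
population_distribution <- function(label, fractions) {
  if (!is.null(names(fractions))) {
    if (!setequal(names(fractions), scenario_labels()))
      stop("fractions must be named by the four scenario labels")
    fractions <- fractions[scenario_labels()]
  } else {
    stopifnot(length(fractions) == 4)
    names(fractions) <- scenario_labels()
  }
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions of '", label, "' sum to ", sum(fractions), ", not 1")
  structure(list(label = as.character(label), fractions = fractions),
            class = "population_distribution")
}

#' @export
print.population_distribution <- function(x, ...) {
  cat("<population_distribution> ", x$label, ": ",
      paste(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read cluster-size distributions from a delimited file
#'
#' Reads a CSV/TSV with columns `label, no_cluster, small, medium, large`
#' giving, per row, the proportion of cells displaying each cluster class.
#' Rows may be percentages (summing to 100) or fractions (summing to 1);
#' the dialect is auto-detected per row from the row sum and ambiguous or
#' inconsistent rows (sum off by more than 0.5%) are rejected by name.
#' Fractions are normalized to sum exactly to 1.
#'
#' A fixture with the five measured Hs578T populations (control, methylene
#' blue, fructose-1,6-bisphosphate, EGF, 2-deoxyglucose) ships with the
#' package: `system.file("extdata", "hs578t_cluster_distributions.csv",
#' package = "glucosim")`.
#'
#' @param source Path to the delimited file (comma or tab separated).
#' @return List of [population_distribution()] objects, one per row.
#' @export
read_distribution <- function(source) {
  first <- readLines(source, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.csv(source, sep = sep, strip.white = TRUE,
                  stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("label", "no_cluster", "small", "medium", "large")
  if (!all(need %in% names(tab)))
    stop("distribution file must have columns: ",
         paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, c("no_cluster", "small", "medium", "large")])
    lab <- tab$label[i]
    total <- sum(v)
    if (abs(total - 100) <= 0.5) {
      v <- v / total
    } else if (abs(total - 1) <= 0.005) {
      v <- v / total
    } else {
      stop("row '", lab, "' sums to ", total,
           ": neither ~100% nor ~1 (within 0.5%)")
    }
    population_distribution(lab, setNames(v, scenario_labels()))
  })
}

#' Ensemble (population-level) product flux
#'
#' Simulates the four cluster scenarios from a common initial state,
#' parameter set and time grid, then mixes the product trajectories with
#' the population fractions:
#' `P_m_ens(t) = sum over scenarios of fraction * P_m_scenario(t)`.
#' Mixing applies to the product levels only; the prediction is a convex
#' combination, so each ensemble level lies between the smallest and
#' largest scenario level at that time.
#'
#' Scenario runs can be precomputed once (e.g. when evaluating many
#' distributions) via `scenario_runs = simulate_scenarios(...)`; results
#' are identical to uncached runs.
#'
#' @param dist A `population_distribution`.
#' @param params,initial,t_end,n_points,... Passed to [simulate_pathway()].
#' @param scenario_runs Optional list of four `glucosome_trajectory`
#'   objects named by scenario, from [simulate_scenarios()].
#' @return An `ensemble_trajectory`: list with `times`, `products`
#'   (`n_points` x 3 matrix over P1..P3), `label`, `fractions` and
#'   `scenario_products` (list of per-scenario product matrices).
#' @export
ensemble_flux <- function(dist, params = default_parameters(),
                          initial = default_initial_state(),
                          t_end = 10, n_points = 1001, ...,
                          scenario_runs = NULL) {
  stopifnot(inherits(dist, "population_distribution"))
  if (is.null(scenario_runs))
    scenario_runs <- simulate_scenarios(params = params, initial = initial,
                                        t_end = t_end, n_points = n_points,
                                        ...)
  if (!setequal(names(scenario_runs), scenario_labels()))
    stop("'scenario_runs' must cover the four scenarios")
  sp <- lapply(scenario_runs[scenario_labels()],
               function(tr) tr$states[, c("P1", "P2", "P3")])
  times <- scenario_runs[[1]]$times
  mixed <- Reduce(`+`, Map(function(f, m) f * m, dist$fractions, sp))
  structure(list(times = times, products = mixed, label = dist$label,
                 fractions = dist$fractions, scenario_products = sp),
            class = "ensemble_trajectory")
}

#' Simulate all four cluster scenarios
#'
#' Convenience wrapper running [simulate_pathway()] once per scenario on a
#' shared grid, initial state and parameter set.
#'
#' @inheritParams simulate_pathway
#' @param ... Passed to [simulate_pathway()].
#' @return Named list of four `glucosome_trajectory` objects.
#' @export
simulate_scenarios <- function(params = default_parameters(),
                               initial = default_initial_state(),
                               t_end = 10, n_points = 1001, ...) {
  lapply(setNames(nm = scenario_labels()), function(sc)
    simulate_pathway(initial, params, sc, t_end = t_end,
                     n_points = n_points, ...))
}

#' @export
print.ensemble_trajectory <- function(x, ...) {
  fin <- x$products[nrow(x$products), ]
  cat("<ensemble_trajectory> ", x$label, " (",
      paste(sprintf("%.1f%%", 100 * x$fractions), collapse = "/"),
      ")\n  products at t_end: P1 = ", signif(fin[1], 4),
      "  P2 = ", signif(fin[2], 4), "  P3 = ", signif(fin[3], 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.ensemble_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$products, label = x$label,
             check.names = FALSE)
}
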