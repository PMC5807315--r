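## Core model definition: state, parameters, the 28 reaction propensities and
## the stoichiometric right-hand side of the 19-variable ODE system.

#' Canonical state variable names
#'
#' The fixed ordering of the 19 model variables used by every matrix,
#' integrator call and serializer in the package: seven metabolic
#' intermediates `S1..S7` (glucose, fructose-6-phosphate,
#' fructose-1,6-bisphosphate, 3-phosphoglycerate, phosphoenolpyruvate,
#' pyruvate, oxaloacetate), nine enzyme species (`E1` free PFKL, `E2` FBPase,
#' `E3` PKM2 dimer, `E4` PEPCK1, `E_S`/`E_M`/`E_L` small/medium/large
#' clusters, `E3_star` PKM2 tetramer, `E1_gly` glycosylated PFKL) and three
#' product pools `P1..P3` (pentose phosphate shunt, serine biosynthesis,
#' glycolytic flux).
#'
#' @return Character vector of length 19.
#' @export
state_names <- function() {
  c(paste0("S", 1:7),
    "E1", "E2", "E3", "E4", "E_S", "E_M", "E_L", "E3_star", "E1_gly",
    "P1", "P2", "P3")
}

#' Canonical rate-constant names
#'
#' Names of the 40 non-dimensional model parameters, in the fixed order used
#' throughout the package (`_m` denotes a backward/minus-subscript rate).
#' Mass-action rate constants `k*`, product formation (`k_p`, `k_s`, `k_f`)
#' and degradation (`delta_p`, `delta_s`, `delta_f`) rates, medium-cluster
#' (`c2`, `c_m2`, `c_m6`, `c_md`) and large-cluster (`e2`, `e_m2`, `e_m6`,
#' `e_md`) catalytic efficiency factors, the allosteric acceleration `alpha`
#' and the three allosteric constants `K1`, `K2`, `K3`.
#'
#' @return Character vector of length 40.
#' @export
parameter_names <- function() {
  c("k0", "k1", "k_m1", "k2", "k_m2", "k3", "k_m3", "k4", "k_m4", "k5",
    "k_m5", "k_m6", "k_as", "k_mas", "k_am", "k_mam", "k_al", "k_mal",
    "k_g", "k_mg", "k_d", "k_md", "k_p", "k_s", "k_f",
    "delta_p", "delta_s", "delta_f",
    "c2", "c_m2", "c_m6", "c_md", "e2", "e_m2", "e_m6", "e_md",
    "alpha", "K1", "K2", "K3")
}

## Efficiency factors zeroed (together with the matching association rates)
## when a scenario excludes medium or large clusters.
medium_efficiency_names <- function() c("c2", "c_m2", "c_m6", "c_md")
large_efficiency_names <- function() c("e2", "e_m2", "e_m6", "e_md")

#' Construct a model state vector
#'
#' Builds a validated `glucosome_state`: a named numeric vector in the
#' canonical order of [state_names()]. All components are non-dimensional
#' concentrations and must be non-negative.
#'
#' @param ... Named scalar overrides of individual state variables.
#' @param values Optional full-length named numeric vector (all 19 names);
#'   `...` overrides are applied on top.
#' @return A `glucosome_state` object (named numeric, length 19).
#' @export
glucosome_state <- function(..., values = NULL) {
  nm <- state_names()
  x <- setNames(numeric(length(nm)), nm)
  if (!is.null(values)) {
    if (!all(nm %in% names(values)))
      stop("'values' must provide all 19 state variables")
    x[nm] <- values[nm]
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), nm)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown state variable(s): ", paste(bad, collapse = ", "))
    x[names(dots)] <- unlist(dots)
  }
  validate_state(x)
  structure(x, class = "glucosome_state")
}

validate_state <- function(x) {
  if (length(x) != 19L || !all(names(x) == state_names()))
    stop("state must be a named numeric vector in canonical order")
  if (any(!is.finite(x))) stop("state contains non-finite values")
  if (any(x < 0))
    stop("negative state component(s): ",
         paste(names(x)[x < 0], collapse = ", "))
  invisible(x)
}

#' Default initial conditions
#'
#' The initial state of the model: all metabolic intermediates and products
#' at a basal level of 0.01, free enzyme pools at (or just below) 100, no
#' clusters, and basal PKM2 tetramer and glycosylated PFKL at 0.01. Each
#' enzyme's total pool (free + modified + clustered, large clusters counting
#' 11-fold) is exactly 100.
#'
#' @return A `glucosome_state`.
#' @seealso [conservation_totals()]
#' @export
default_initial_state <- function() {
  glucosome_state(values = setNames(
    c(rep(0.01, 7), 99.99, 100, 99.99, 100, 0, 0, 0, 0.01, 0.01,
      0.01, 0.01, 0.01),
    state_names()))
}

#' Construct a model parameter set
#'
#' Builds a validated `glucosome_params`: a named numeric vector over
#' [parameter_names()], starting from the model defaults (see
#' [default_parameters()]) with optional overrides. All rate constants are
#' non-negative and non-dimensional.
#'
#' @param ... Named scalar overrides of individual rate constants.
#' @param values Optional full-length named numeric vector; `...` applies
#'   on top.
#' @return A `glucosome_params` object (named numeric, length 40).
#' @export
glucosome_parameters <- function(..., values = NULL) {
  p <- unclass(default_parameters())
  if (!is.null(values)) {
    nm <- parameter_names()
    if (!all(nm %in% names(values)))
      stop("'values' must provide all 40 parameters")
    p[nm] <- values[nm]
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), parameter_names())
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  validate_parameters(p)
  structure(p, class = "glucosome_params")
}

validate_parameters <- function(p) {
  if (length(p) != 40L || !all(names(p) == parameter_names()))
    stop("parameters must be a named numeric vector in canonical order")
  if (any(!is.finite(p))) stop("parameters contain non-finite values")
  if (any(p < 0))
    stop("negative parameter(s): ", paste(names(p)[p < 0], collapse = ", "))
  invisible(p)
}

#' Default rate constants
#'
#' The model's default non-dimensional rate constants. Generic enzymatic
#' steps are set to 10; `k2`/`k_m2` (40/7) and `k4`/`k_m4` (14/7) are tuned
#' so that glycolysis dominates in the absence of clusters; product
#' formation and degradation rates are 5 and 0.5; medium-cluster
#' efficiencies decelerate glycolysis (`c2 = 0.2`, `c_md = 0.1`) and
#' accelerate gluconeogenesis (`c_m2 = c_m6 = 10`); large-cluster
#' efficiencies redirect flux toward serine biosynthesis (`e2 = 2.5`,
#' `e_m6 = 10`, `e_m2 = 0.1`, `e_md = 0.05`); allosteric constants are 1.
#'
#' @return A `glucosome_params`.
#' @export
default_parameters <- function() {
  structure(setNames(
    c(10, 10, 10, 40, 7, 10, 10, 14, 7, 1,
      10, 10, 10, 10, 10, 10, 10, 10,
      1, 1, 1, 1, 5, 5, 5,
      0.5, 0.5, 0.5,
      0.2, 10, 10, 0.1, 2.5, 0.1, 10, 0.05,
      1, 1, 1, 1),
    parameter_names()), class = "glucosome_params")
}

#' Reaction propensities
#'
#' Evaluates the 28 deterministic reaction propensities R1..R28 at a given
#' state. R1..R12 are the metabolic interconversions (R4, R5 and R12 carry
#' the cluster-efficiency weighted enzyme pools and, for R4/R5, hyperbolic
#' allosteric inhibition terms), R13..R18 cluster
#' association/disassociation (R15 assembles a medium cluster from a small
#' PFKL cluster plus one FBPase, PKM2 and PEPCK1; R17 condenses 11 medium
#' clusters into one large cluster), R19/R20 PFKL
#' glycosylation/de-glycosylation, R21/R22 PKM2 tetramer/dimer
#' interconversion (R22 allosterically promoted by fructose-1,6-bisphosphate),
#' R23..R25 product formation and R26..R28 product degradation.
#'
#' @param state A non-negative `glucosome_state` (or named numeric vector in
#'   canonical order). Negative components are rejected.
#' @param params A `glucosome_params` (or named numeric vector).
#' @return Named numeric vector `R1..R28`, all non-negative.
#' @export
propensities <- function(state, params = default_parameters()) {
  s <- as.numeric(state[state_names()])
  names(s) <- state_names()
  validate_state(s)
  p <- as.numeric(params[parameter_names()])
  names(p) <- parameter_names()
  validate_parameters(p)
  propensities_raw(s, p)
}

## Unchecked evaluation used by the R integrator fallback; clips negatives so
## the RHS stays defined if the solver steps slightly below zero (the 11th
## power in R17 amplifies tiny negative excursions).
propensities_raw <- function(s, p) {
  s[s < 0] <- 0
  R <- numeric(28)
  R[1] <- p[["k0"]]
  R[2] <- p[["k1"]] * s[["S1"]]
  R[3] <- p[["k_m1"]] * s[["S2"]]
  R[4] <- p[["k2"]] *
    (s[["E1"]] + s[["E_S"]] + p[["c2"]] * s[["E_M"]] + p[["e2"]] * s[["E_L"]]) *
    s[["S2"]] * p[["K1"]] / (p[["K1"]] + s[["S3"]])
  R[5] <- p[["k_m2"]] *
    (s[["E2"]] + p[["c_m2"]] * s[["E_M"]] + p[["e_m2"]] * s[["E_L"]]) *
    s[["S3"]] * p[["K2"]] / (p[["K2"]] + s[["S2"]])
  R[6] <- p[["k3"]] * s[["S3"]]
  R[7] <- p[["k_m3"]] * s[["S4"]]
  R[8] <- p[["k4"]] * s[["S4"]]
  R[9] <- p[["k_m4"]] * s[["S5"]]
  R[10] <- p[["k5"]] * s[["E3_star"]] * s[["S5"]]
  R[11] <- p[["k_m5"]] * s[["S6"]]
  R[12] <- p[["k_m6"]] *
    (s[["E4"]] + p[["c_m6"]] * s[["E_M"]] + p[["e_m6"]] * s[["E_L"]]) * s[["S7"]]
  R[13] <- p[["k_as"]] * s[["E1"]]
  R[14] <- p[["k_mas"]] * s[["E_S"]]
  R[15] <- p[["k_am"]] * s[["E_S"]] * s[["E2"]] * s[["E3"]] * s[["E4"]]
  R[16] <- p[["k_mam"]] * s[["E_M"]]
  R[17] <- p[["k_al"]] * s[["E_M"]]^11
  R[18] <- p[["k_mal"]] * s[["E_L"]]
  R[19] <- p[["k_g"]] * s[["E1"]]
  R[20] <- p[["k_mg"]] * s[["E1_gly"]]
  R[21] <- p[["k_d"]] * s[["E3_star"]]
  R[22] <- p[["k_md"]] *
    (s[["E3"]] + p[["c_md"]] * s[["E_M"]] + p[["e_md"]] * s[["E_L"]]) *
    (1 + p[["alpha"]] * s[["S3"]] / (s[["S3"]] + p[["K3"]]))
  R[23] <- p[["k_p"]] * s[["S2"]]
  R[24] <- p[["k_s"]] * s[["S4"]]
  R[25] <- p[["k_f"]] * s[["S6"]]
  R[26] <- p[["delta_p"]] * s[["P1"]]
  R[27] <- p[["delta_s"]] * s[["P2"]]
  R[28] <- p[["delta_f"]] * s[["P3"]]
  names(R) <- paste0("R", 1:28)
  R
}

#' Stoichiometry of the ODE system
#'
#' The three stoichiometry blocks of the model and the propensity indices
#' they consume. `nu_S` (7 x 15) maps the metabolic propensities
#' (R1..R12, R23..R25) onto the intermediates, `nu_E` (9 x 10) maps the
#' enzyme/cluster propensities (R13..R22) onto the enzyme species -- with
#' +/-11 entries in the `E_M` row coupling the 11-to-1 medium-to-large
#' condensation -- and `nu_P` (3 x 6) maps formation/degradation
#' (R23..R28) onto the products. R23..R25 appear in both `nu_S` and `nu_P`:
#' one propensity evaluation feeds both blocks.
#'
#' @return A list with matrices `nu_S`, `nu_E`, `nu_P` (dimnames set to
#'   state-variable rows and reaction columns) and integer index vectors
#'   `reactions_S`, `reactions_E`, `reactions_P` into the 28-vector of
#'   propensities.
#' @export
stoichiometry <- function() {
  reactions_S <- c(1:12, 23:25)
  reactions_E <- 13:22
  reactions_P <- 23:28
  nu_S <- matrix(c(
    1, -1,  1,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,
    0,  1, -1, -1,  1,  0,  0,  0,  0,  0,  0,  0, -1,  0,  0,
    0,  0,  0,  1, -1, -1,  1,  0,  0,  0,  0,  0,  0,  0,  0,
    0,  0,  0,  0,  0,  1, -1, -1,  1,  0,  0,  0,  0, -1,  0,
    0,  0,  0,  0,  0,  0,  0,  1, -1, -1,  0,  1,  0,  0,  0,
    0,  0,  0,  0,  0,  0,  0,  0,  0,  1, -1,  0,  0,  0, -1,
    0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  1, -1,  0,  0,  0),
    nrow = 7, byrow = TRUE,
    dimnames = list(state_names()[1:7], paste0("R", reactions_S)))
  nu_E <- matrix(c(
    -1,  1,  0,  0,   0,  0, -1,  1,  0,  0,
     0,  0, -1,  1,   0,  0,  0,  0,  0,  0,
     0,  0, -1,  1,   0,  0,  0,  0,  1, -1,
     0,  0, -1,  1,   0,  0,  0,  0,  0,  0,
     1, -1, -1,  1,   0,  0,  0,  0,  0,  0,
     0,  0,  1, -1, -11, 11,  0,  0,  0,  0,
     0,  0,  0,  0,   1, -1,  0,  0,  0,  0,
     0,  0,  0,  0,   0,  0,  0,  0, -1,  1,
     0,  0,  0,  0,   0,  0,  1, -1,  0,  0),
    nrow = 9, byrow = TRUE,
    dimnames = list(state_names()[8:16], paste0("R", reactions_E)))
  nu_P <- matrix(c(
    1, 0, 0, -1,  0,  0,
    0, 1, 0,  0, -1,  0,
    0, 0, 1,  0,  0, -1),
    nrow = 3, byrow = TRUE,
    dimnames = list(state_names()[17:19], paste0("R", reactions_P)))
  list(nu_S = nu_S, nu_E = nu_E, nu_P = nu_P,
       reactions_S = reactions_S, reactions_E = reactions_E,
       reactions_P = reactions_P)
}

.stoich <- NULL  # memoized at first use

get_stoich <- function() {
  if (is.null(.stoich)) utils::assignInMyNamespace(".stoich", stoichiometry())
  .stoich
}

#' Time derivative of the model state
#'
#' Evaluates the right-hand side of the ODE system: `dS/dt = nu_S R_S`,
#' `dE/dt = nu_E R_E`, `dP/dt = nu_P R_P`, with the stoichiometry blocks of
#' [stoichiometry()] applied to the propensity sub-vectors.
#'
#' @inheritParams propensities
#' @return Named numeric vector of length 19: the rate of change of each
#'   state variable.
#' @export
derivative <- function(state, params = default_parameters()) {
  R <- propensities(state, params)
  nu <- get_stoich()
  dy <- c(drop(nu$nu_S %*% R[nu$reactions_S]),
          drop(nu$nu_E %*% R[nu$reactions_E]),
          drop(nu$nu_P %*% R[nu$reactions_P]))
  names(dy) <- state_names()
  dy
}

## RHS in deSolve's (t, y, parms) signature; pure-R integration route.
rhs_r <- function(t, y, parms) {
  R <- propensities_raw(setNames(y, state_names()),
                        setNames(parms, parameter_names()))
  nu <- get_stoich()
  list(c(drop(nu$nu_S %*% R[nu$reactions_S]),
         drop(nu$nu_E %*% R[nu$reactions_E]),
         drop(nu$nu_P %*% R[nu$reactions_P])))
}

#' Enzyme conservation totals
#'
#' The total pool of each glucosome member enzyme, counting its free,
#' modified and clustered forms; a large cluster contains 11 copies of each
#' member (it condenses 11 medium clusters). Along any trajectory each total
#' is conserved; from the default initial state each equals 100.
#'
#' @param state A `glucosome_state` or named numeric vector (also accepts a
#'   matrix with canonical column names, returning one row of totals per
#'   state row).
#' @return Named numeric vector `c(PFK, FBPase, PK, PEPCK)` (or a 4-column
#'   matrix for matrix input).
#' @export
conservation_totals <- function(state) {
  if (is.matrix(state)) {
    out <- cbind(
      PFK = state[, "E1"] + state[, "E1_gly"] + state[, "E_S"] +
        state[, "E_M"] + 11 * state[, "E_L"],
      FBPase = state[, "E2"] + state[, "E_M"] + 11 * state[, "E_L"],
      PK = state[, "E3"] + state[, "E3_star"] + state[, "E_M"] +
        11 * state[, "E_L"],
      PEPCK = state[, "E4"] + state[, "E_M"] + 11 * state[, "E_L"])
    return(out)
  }
  c(PFK = unname(state[["E1"]] + state[["E1_gly"]] + state[["E_S"]] +
                   state[["E_M"]] + 11 * state[["E_L"]]),
    FBPase = unname(state[["E2"]] + state[["E_M"]] + 11 * state[["E_L"]]),
    PK = unname(state[["E3"]] + state[["E3_star"]] + state[["E_M"]] +
                  11 * state[["E_L"]]),
    PEPCK = unname(state[["E4"]] + state[["E_M"]] + 11 * state[["E_L"]]))
}

#' @export
print.glucosome_state <- function(x, ...) {
  cat("<glucosome_state> 19 variables (non-dimensional)\n")
  print(round(unclass(x), 6), ...)
  invisible(x)
}

#' @export
print.glucosome_params <- function(x, ...) {
  cat("<glucosome_params> 40 rate constants (non-dimensional)\n")
  print(unclass(x), ...)
  invisible(x)
}
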