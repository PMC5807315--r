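## Global sensitivity analysis: Latin hypercube sampling of the rate
## constants and partial rank correlation coefficients (PRCC) against the
## end-time product concentrations.

#' Latin hypercube sample of the model parameters
#'
#' Draws a stratified Latin hypercube sample of the rate constants: each
#' parameter with default `d` is sampled uniformly on `[d/2, 2d]`, with
#' exactly one draw per equal-probability bin per parameter. Parameters in
#' `exclude` are held at their defaults. A parameter with default 0 cannot
#' be sampled (its interval is degenerate) and must be excluded.
#'
#' @param defaults `glucosome_params` supplying the default values (and the
#'   set of sampled parameters).
#' @param n_samples Number of samples, >= 2.
#' @param seed Integer seed; fixed seed gives an identical sample matrix.
#'   The caller's RNG state is left untouched.
#' @param exclude Character vector of parameter names to hold fixed.
#' @return A `parameter_samples`: list with `matrix` (`n_samples` x
#'   `n_parameters`, colnames = sampled parameter names), `bounds` (2 x
#'   `n_parameters`, rows `lo`/`hi`), `defaults`, `excluded`, `seed`.
#' @export
lhs_sample <- function(defaults = default_parameters(), n_samples, seed,
                       exclude = character()) {
  stopifnot(n_samples >= 2)
  bad <- setdiff(exclude, parameter_names())
  if (length(bad)) stop("unknown parameter(s) in 'exclude': ",
                        paste(bad, collapse = ", "))
  sampled <- setdiff(parameter_names(), exclude)
  d <- unclass(defaults)[sampled]
  if (any(d == 0))
    stop("parameter(s) with default 0 cannot be sampled on [d/2, 2d]: ",
         paste(sampled[d == 0], collapse = ", "), " (add to 'exclude')")
  lo <- d / 2
  hi <- 2 * d
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(as.integer(n_samples), length(sampled))
  m <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(m) <- sampled
  structure(list(matrix = m,
                 bounds = rbind(lo = lo, hi = hi),
                 defaults = defaults, excluded = exclude,
                 seed = as.integer(seed)),
            class = "parameter_samples")
}

#' @export
print.parameter_samples <- function(x, ...) {
  cat("<parameter_samples> ", nrow(x$matrix), " Latin hypercube draws of ",
      ncol(x$matrix), " parameters on [d/2, 2d], seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Simulate every parameter sample
#'
#' Runs the model once per sample row (non-sampled parameters at their
#' defaults) and records the three product concentrations at the end time.
#'
#' @param samples A `parameter_samples` from [lhs_sample()].
#' @param scenario Cluster scenario for every run; `LARGE` (the full model,
#'   all parameters active) by default.
#' @param t_end End time of each simulation.
#' @param initial Initial state for every run.
#' @param ... Further arguments to [simulate_pathway()].
#' @return Numeric matrix `n_samples` x 3, columns `P1`, `P2`, `P3`.
#' @export
evaluate_samples <- function(samples, scenario = "LARGE", t_end = 10,
                             initial = default_initial_state(), ...) {
  stopifnot(inherits(samples, "parameter_samples"))
  m <- samples$matrix
  out <- matrix(NA_real_, nrow(m), 3,
                dimnames = list(NULL, c("P1", "P2", "P3")))
  base <- unclass(samples$defaults)
  for (i in seq_len(nrow(m))) {
    p <- base
    p[colnames(m)] <- m[i, ]
    tr <- tryCatch(
      simulate_pathway(initial, glucosome_parameters(values = p), scenario,
                       t_end = t_end, n_points = 2, ...),
      error = function(e) stop("simulation failed for sample ", i, ": ",
                               conditionMessage(e)))
    out[i, ] <- tr$states[2, c("P1", "P2", "P3")]
  }
  out
}

#' Partial rank correlation coefficients
#'
#' For each (parameter, product) pair, computes the partial correlation of
#' the rank-transformed parameter column with the rank-transformed output
#' column, controlling for the ranks of all other parameter columns. Ranks
#' use average ties. The implementation inverts the correlation matrix of
#' the ranked columns (precision-matrix route). The p-value is the two-sided
#' t-test on `t = prcc * sqrt((n - 2 - k) / (1 - prcc^2))` with `k` the
#' number of controlled parameters and `n - 2 - k` degrees of freedom.
#'
#' A constant parameter column has no defined PRCC: it is reported as `NA`,
#' flagged not sensitive, with a warning.
#'
#' @param samples A `parameter_samples` (or plain numeric matrix with column
#'   names).
#' @param outputs Numeric matrix of model outputs, one column per output
#'   (e.g. from [evaluate_samples()]), `n_samples` rows.
#' @param threshold,alpha Sensitivity classification passed to
#'   [classify_sensitive()].
#' @return A `prcc_table`: data frame with columns `parameter`, `product`,
#'   `prcc`, `p_value`, `sensitive`.
#' @export
prcc <- function(samples, outputs, threshold = 0.2, alpha = 0.01) {
  X <- if (inherits(samples, "parameter_samples")) samples$matrix else samples
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  outputs <- as.matrix(outputs)
  if (is.null(colnames(outputs)))
    colnames(outputs) <- paste0("Y", seq_len(ncol(outputs)))
  n <- nrow(X)
  if (nrow(outputs) != n) stop("'samples' and 'outputs' row counts differ")
  if (n <= ncol(X) + 2)
    stop("need n_samples > n_parameters + 2 for the PRCC t-test")
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant parameter column(s), PRCC undefined: ",
            paste(colnames(X)[const], collapse = ", "))
  Xr <- apply(X[, !const, drop = FALSE], 2, rank)
  k <- ncol(Xr) - 1L          # parameters controlled for
  df <- n - 2L - k
  res <- expand.grid(parameter = colnames(X), product = colnames(outputs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$prcc <- NA_real_
  res$p_value <- NA_real_
  for (m in colnames(outputs)) {
    yr <- rank(outputs[, m])
    if (diff(range(yr)) == 0) next   # constant output: undefined, left NA
    if (ncol(Xr) == 1L) {
      # nothing to control for: the PRCC is the plain Spearman correlation
      pr <- setNames(cor(Xr[, 1], yr), colnames(Xr))
    } else {
      C <- cor(cbind(Xr, .y = yr))
      P <- tryCatch(solve(C), error = function(e)
        stop("rank-correlation matrix is singular ",
             "(collinear parameter ranks): ", conditionMessage(e)))
      j_y <- ncol(P)
      pr <- -P[seq_len(ncol(Xr)), j_y] /
        sqrt(diag(P)[seq_len(ncol(Xr))] * P[j_y, j_y])
    }
    pr <- pmin(1, pmax(-1, pr))
    tstat <- pr * sqrt(pmax(df, 0) / pmax(1 - pr^2, .Machine$double.eps))
    pval <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
    pval[abs(pr) >= 1] <- 0
    rows <- res$product == m & res$parameter %in% colnames(Xr)
    ord <- match(res$parameter[rows], colnames(Xr))
    res$prcc[rows] <- unname(pr)[ord]
    res$p_value[rows] <- unname(pval)[ord]
  }
  classify_sensitive(structure(res, class = c("prcc_table", "data.frame")),
                     threshold = threshold, alpha = alpha)
}

#' Flag sensitive parameters
#'
#' Re-derives the `sensitive` flag of a PRCC table: a (parameter, product)
#' pair is sensitive iff `|PRCC| > threshold` and `p < alpha`. Undefined
#' (`NA`) PRCCs are never sensitive.
#'
#' @param table A `prcc_table` from [prcc()].
#' @param threshold Magnitude threshold on `|PRCC|` (default 0.2).
#' @param alpha Significance level on the p-value (default 0.01).
#' @return The table with its `sensitive` column set.
#' @export
classify_sensitive <- function(table, threshold = 0.2, alpha = 0.01) {
  stopifnot(is.data.frame(table),
            all(c("prcc", "p_value") %in% names(table)))
  table$sensitive <- !is.na(table$prcc) & !is.na(table$p_value) &
    abs(table$prcc) > threshold & table$p_value < alpha
  if (!inherits(table, "prcc_table"))
    class(table) <- c("prcc_table", class(table))
  table
}

#' @export
print.prcc_table <- function(x, ...) {
  cat("<prcc_table> ", length(unique(x$parameter)), " parameters x ",
      length(unique(x$product)), " outputs; ",
      sum(x$sensitive), " sensitive pair(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Finite-difference sensitivity at the defaults
#'
#' Central finite-difference derivative of each end-time product with
#' respect to one parameter, at the default parameter values. Used to
#' cross-check PRCC signs against direct local perturbation.
#'
#' @param name Parameter name.
#' @param scenario,t_end,params,initial As in [simulate_pathway()].
#' @param rel Relative step size (default 1%% of the default value).
#' @return Named numeric vector: `d(P1,P2,P3)/d(name)` at the defaults.
#' @export
finite_difference_sensitivity <- function(name, scenario = "LARGE",
                                          t_end = 10,
                                          params = default_parameters(),
                                          initial = default_initial_state(),
                                          rel = 0.01) {
  if (!name %in% parameter_names()) stop("unknown parameter: ", name)
  d <- unclass(params)[[name]]
  if (d == 0) stop("finite difference undefined at a zero default")
  h <- rel * d
  p_hi <- params; p_hi[name] <- d + h
  p_lo <- params; p_lo[name] <- d - h
  f <- function(p) simulate_pathway(initial, p, scenario, t_end = t_end,
                                    n_points = 2)$states[2, c("P1", "P2", "P3")]
  (f(p_hi) - f(p_lo)) / (2 * h)
}
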