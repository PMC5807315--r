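## Serialization: flat key-value records for states and parameter sets
## (JSON or two-column CSV, chosen by file extension), long/wide trajectory
## CSVs with round-trip readers, and the PRCC / ensemble report writers.

flat_write <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(unclass(x)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(name = names(x), value = as.numeric(x)),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

flat_read <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- unlist(jsonlite::read_json(path))
    setNames(as.numeric(v), names(v))
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    setNames(as.numeric(tab$value), tab$name)
  }
}

#' Write / read a state vector
#'
#' Serializes a `glucosome_state` as a flat name-to-value record, JSON
#' (`.json`) or two-column CSV (`name,value`) by extension.
#'
#' @param state A `glucosome_state`.
#' @param path Output/input file path.
#' @return `write_state()` the path, invisibly; `read_state()` a validated
#'   `glucosome_state`.
#' @export
write_state <- function(state, path) flat_write(state[state_names()], path)

#' @rdname write_state
#' @export
read_state <- function(path) glucosome_state(values = flat_read(path))

#' Write / read a parameter set
#'
#' Serializes a `glucosome_params` as a flat name-to-value record, JSON
#' (`.json`) or two-column CSV by extension.
#'
#' @param params A `glucosome_params`.
#' @param path Output/input file path.
#' @return `write_parameters()` the path, invisibly; `read_parameters()` a
#'   validated `glucosome_params`.
#' @export
write_parameters <- function(params, path)
  flat_write(params[parameter_names()], path)

#' @rdname write_parameters
#' @export
read_parameters <- function(path) glucosome_parameters(values = flat_read(path))

#' Write / read a trajectory
#'
#' `wide` format has one row per time point and one column per state
#' variable plus `time` and `scenario`; `long` format has columns
#' `time, variable, value, scenario`. `read_trajectory()` auto-detects the
#' format and always returns the wide data frame.
#'
#' @param traj A `glucosome_trajectory`.
#' @param path CSV path.
#' @param format `"wide"` (default) or `"long"`.
#' @return `write_trajectory()` the path, invisibly; `read_trajectory()` a
#'   wide data frame (`time`, the 19 state columns, `scenario`).
#' @export
write_trajectory <- function(traj, path, format = c("wide", "long")) {
  format <- match.arg(format)
  wide <- as.data.frame(traj)
  if (format == "wide") {
    write.csv(wide, path, row.names = FALSE, quote = FALSE)
  } else {
    long <- data.frame(
      time = rep(wide$time, times = 19),
      variable = rep(state_names(), each = nrow(wide)),
      value = as.vector(as.matrix(wide[state_names()])),
      scenario = traj$scenario)
    write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("variable", "value") %in% names(tab))) {
    wide <- data.frame(time = sort(unique(tab$time)))
    for (v in state_names())
      wide[[v]] <- tab$value[tab$variable == v][order(tab$time[tab$variable == v])]
    wide$scenario <- tab$scenario[1]
    tab <- wide
  }
  if (!all(c("time", state_names()) %in% names(tab)))
    stop("not a glucosim trajectory file: ", path)
  tab
}

#' Write a PRCC report
#'
#' CSV with columns `parameter, product, prcc, p_value, sensitive`.
#'
#' @param table A `prcc_table`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_prcc <- function(table, path) {
  write.csv(table[, c("parameter", "product", "prcc", "p_value",
                      "sensitive")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ensemble trajectory
#'
#' CSV with columns `time, P1, P2, P3, label`.
#'
#' @param ens An `ensemble_trajectory`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  write.csv(as.data.frame(ens), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep envelope
#'
#' Long CSV with columns
#' `scenario, time, product, min, max`: the per-time-point envelope of each
#' product across the sweep grid.
#'
#' @param env A `sweep_envelope`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_envelope <- function(env, path) {
  rows <- do.call(rbind, lapply(names(env$scenarios), function(sc) {
    e <- env$scenarios[[sc]]
    do.call(rbind, lapply(c("P1", "P2", "P3"), function(pr)
      data.frame(scenario = sc, time = env$times, product = pr,
                 min = e$min[, pr], max = e$max[, pr])))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
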