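## Configuration handling and file writers. Configs are JSON with an explicit
## schema_version; unknown keys are rejected rather than ignored so typos
## fail loudly. All CSV output keeps full double precision.

config_defaults <- function() {
  list(t_end = 2000, n_points = 201, seed = 1L)
}

known_config_keys <- function() {
  c("schema_version", "model", "params", "initial", "N", "t_end", "n_points",
    "seed", "output_path")
}

#' Load and validate a run configuration
#'
#' Reads a JSON run configuration, applies defaults for omitted integration
#' controls (`t_end = 2000`, `n_points = 201`, `seed = 1`), and validates the
#' result: known keys only, a recognised model variant, admissible rates, and
#' an initial state whose components sum to `N`. All validation failures are
#' reported together; nothing is silently corrected.
#'
#' @param path path to a JSON configuration file.
#' @param quiet suppress the informational message listing applied defaults.
#' @return A `sosa_config` list: `model` (`"sisa"`, `"sosa_spsa"` or
#'   `"modified"`), `params`, `initial`, `N`, `t_end`, `n_points`, `seed`,
#'   `output_path` (may be NA).
#' @export
#' @examples
#' cfg <- load_config(fhs_config_path())
#' cfg$N
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("config parse error in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  problems <- character(0)
  unknown <- setdiff(names(raw), known_config_keys())
  if (length(unknown) > 0) {
    problems <- c(problems,
                  sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$schema_version) || raw$schema_version != 1) {
    problems <- c(problems, "schema_version must be 1")
  }
  model <- if (is.null(raw$model)) "modified" else raw$model
  if (!model %in% c("sisa", "sosa_spsa", "modified")) {
    problems <- c(problems, sprintf("unknown model variant: %s", model))
  }
  if (is.null(raw$params) || is.null(raw$initial) || is.null(raw$N)) {
    problems <- c(problems, "config must supply params, initial and N")
    stop(paste(problems, collapse = "; "), call. = FALSE)
  }
  defaults <- config_defaults()
  applied <- setdiff(names(defaults), names(raw))
  for (k in applied) raw[[k]] <- defaults[[k]]
  if (!quiet && length(applied) > 0) {
    message("config defaults applied: ",
            paste(sprintf("%s = %s", applied, unlist(defaults[applied])),
                  collapse = ", "))
  }
  params <- tryCatch({
    pl <- raw$params
    if (model == "sisa") {
      # single-channel variant: one alpha/beta/g triple, mapped onto the
      # optimistic channel with the pessimistic channel switched off
      need <- c("alpha", "beta", "g")
      if (!all(need %in% names(pl))) {
        stop("model 'sisa' requires params alpha, beta, g")
      }
      pl <- c(list(alpha_O = pl$alpha, beta_O = pl$beta, g_O = pl$g,
                   alpha_P = 0, beta_P = 0, g_P = 0),
              pl[intersect("contact_scaling", names(pl))])
    }
    if (model == "sosa_spsa") {
      extra <- intersect(c("l1", "l2", "m1", "m2"), names(pl))
      nonzero <- extra[vapply(extra, function(k) pl[[k]] != 0, logical(1))]
      if (length(nonzero) > 0) {
        problems <- c(problems,
                      sprintf("model 'sosa_spsa' forbids interaction rates: %s",
                              paste(nonzero, collapse = ", ")))
      }
    }
    do.call(model_parameters, pl)
  }, error = function(e) {
    problems <<- c(problems, sprintf("params: %s", conditionMessage(e)))
    NULL
  })
  if (!is.null(params)) {
    problems <- c(problems, as.character(validate_parameters(params)))
  }
  init <- unlist(raw$initial)
  if (!all(c("S", "O", "P") %in% names(init))) {
    problems <- c(problems, "initial must have components S, O, P")
  } else if (any(init[c("S", "O", "P")] < 0)) {
    problems <- c(problems, "initial components must be nonnegative")
  } else if (abs(sum(init[c("S", "O", "P")]) - raw$N) > 1e-8 * raw$N) {
    problems <- c(problems,
                  sprintf("initial state breaks conservation: S+O+P = %g but N = %g",
                          sum(init[c("S", "O", "P")]), raw$N))
  }
  if (!is.null(raw$t_end) && raw$t_end <= 0) {
    problems <- c(problems, "t_end must be positive")
  }
  if (length(problems) > 0) {
    stop("invalid config: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  init <- stats::setNames(as.numeric(init[c("S", "O", "P")]),
                          c("S", "O", "P"))
  structure(list(model = model, params = params,
                 initial = init, N = as.numeric(raw$N),
                 t_end = as.numeric(raw$t_end),
                 n_points = as.numeric(raw$n_points),
                 seed = as.integer(raw$seed),
                 output_path = if (is.null(raw$output_path)) NA_character_
                               else raw$output_path),
            class = "sosa_config")
}

#' Write a run configuration back to JSON
#'
#' Inverse of [load_config()]: a configuration written and re-loaded is
#' field-identical.
#'
#' @param config a `sosa_config` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sosa_config"))
  p <- config$params
  doc <- list(schema_version = 1,
              model = config$model,
              params = c(p[rate_names()],
                         list(contact_scaling = p$contact_scaling)),
              initial = as.list(config$initial),
              N = config$N,
              t_end = config$t_end,
              n_points = config$n_points,
              seed = config$seed)
  if (!is.na(config$output_path)) doc$output_path <- config$output_path
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
}

write_precise_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Trajectory, sweep, event-log and ensemble writers
#'
#' CSV writers preserving full double precision (17 significant digits).
#' `write_trajectory_csv` emits `t,S,O,P` in counts, or compartment fractions
#' when `fractions = TRUE`. `write_equilibrium_json` emits a flat JSON record
#' of an equilibrium result.
#'
#' @param traj a `sosa_trajectory`.
#' @param path destination file.
#' @param fractions write compartments as fractions of N instead of counts.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, fractions = FALSE) {
  df <- as.data.frame(traj)[, c("t", "S", "O", "P")]
  if (fractions) {
    N <- attr(traj, "N")
    df[, c("S", "O", "P")] <- df[, c("S", "O", "P")] / N
  }
  write_precise_csv(df, path)
}

#' @rdname write_trajectory_csv
#' @param eq a `sosa_equilibrium`.
#' @export
write_equilibrium_json <- function(eq, path) {
  stopifnot(inherits(eq, "sosa_equilibrium"))
  rec <- list(S = eq$state[["S"]], O = eq$state[["O"]], P = eq$state[["P"]],
              residual_rhs = eq$residual_rhs,
              residual_eq2 = eq$residual_eq2)
  if (!is.null(eq$eigenvalues)) {
    rec$eigenvalues_re <- Re(eq$eigenvalues)
    rec$eigenvalues_im <- Im(eq$eigenvalues)
    rec$stable <- eq$stable
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param sweep a `sosa_sweep`.
#' @export
write_sweep_csv <- function(sweep, path) {
  write_precise_csv(as.data.frame(sweep), path)
}

#' @rdname write_trajectory_csv
#' @param run a `sosa_events` object.
#' @export
write_events_csv <- function(run, path) {
  write_precise_csv(run$events[, c("t", "event", "S", "O", "P")], path)
}

#' @rdname write_trajectory_csv
#' @param ensemble a data.frame from [ensemble_mean()].
#' @export
write_ensemble_csv <- function(ensemble, path) {
  write_precise_csv(ensemble, path)
}
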