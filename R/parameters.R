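#' Contagion rate parameters for the modified SOSa-SPSa model
#'
#' Bundles the ten rates of the three-compartment sentiment-contagion model:
#' two SISa-style channels (susceptible-optimistic and susceptible-pessimistic,
#' each with spontaneous adoption `alpha`, contact transmission `beta` and
#' recovery `g`) plus four interaction rates governing what happens when an
#' optimist meets a pessimist (`l1`: optimist reverts to susceptible, `l2`:
#' optimist turns pessimistic) or a pessimist meets an optimist (`m1`:
#' pessimist reverts to susceptible, `m2`: pessimist turns optimistic).
#'
#' All rates are per unit time; time units are abstract. `contact_scaling`
#' selects frequency-dependent transmission (bilinear contact terms divided by
#' the population size N, the default) or density-dependent transmission (raw
#' count products).
#'
#' @param alpha_O spontaneous optimism rate.
#' @param beta_O optimistic transmission rate per contact.
#' @param g_O optimist recovery rate (optimistic to susceptible).
#' @param alpha_P spontaneous pessimism rate.
#' @param beta_P pessimistic transmission rate per contact.
#' @param g_P pessimist recovery rate (pessimistic to susceptible).
#' @param l1 rate that an optimist meeting a pessimist becomes susceptible.
#' @param l2 rate that an optimist meeting a pessimist becomes pessimistic.
#' @param m1 rate that a pessimist meeting an optimist becomes susceptible.
#' @param m2 rate that a pessimist meeting an optimist becomes optimistic.
#' @param contact_scaling `"frequency"` (contact terms / N) or `"density"`.
#'
#' @return An object of class `sosa_params` (a named list of the ten rates and
#'   the scaling convention).
#' @seealso [validate_parameters()], [modified_rhs()], [fhs_parameters()]
#' @export
#' @examples
#' p <- model_parameters(alpha_O = 0.18, beta_O = 0.02, g_O = 0.088,
#'                       alpha_P = 0.04, beta_P = 0.04, g_P = 0.13,
#'                       l1 = 0.13, l2 = 0.009, m1 = 0.09, m2 = 0.07)
#' validate_parameters(p)
model_parameters <- function(alpha_O, beta_O, g_O, alpha_P, beta_P, g_P,
                             l1 = 0, l2 = 0, m1 = 0, m2 = 0,
                             contact_scaling = c("frequency", "density")) {
  contact_scaling <- match.arg(contact_scaling)
  p <- list(alpha_O = alpha_O, beta_O = beta_O, g_O = g_O,
            alpha_P = alpha_P, beta_P = beta_P, g_P = g_P,
            l1 = l1, l2 = l2, m1 = m1, m2 = m2,
            contact_scaling = contact_scaling)
  num <- p[rate_names()]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("all rates must be finite numeric scalars", call. = FALSE)
  }
  class(p) <- "sosa_params"
  p
}

rate_names <- function() {
  c("alpha_O", "beta_O", "g_O", "alpha_P", "beta_P", "g_P",
    "l1", "l2", "m1", "m2")
}

#' Check model parameters against their structural constraints
#'
#' Report-style validation: every violated constraint is listed; an empty
#' report means the parameter set is admissible. Constraints are
#' nonnegativity of all ten rates and the interaction-probability budgets
#' `l1 + l2 <= 1` and `m1 + m2 <= 1`.
#'
#' @param params a [model_parameters()] object.
#' @return Character vector of violation messages, empty when valid, with
#'   class `sosa_validation`. Use [is_valid()] for a logical answer.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "sosa_params"))
  violations <- character(0)
  for (nm in rate_names()) {
    if (params[[nm]] < 0) {
      violations <- c(violations, sprintf("negative rate: %s = %g", nm,
                                          params[[nm]]))
    }
  }
  if (params$l1 + params$l2 > 1) {
    violations <- c(violations,
                    sprintf("l1+l2>1 (l1 = %g, l2 = %g)", params$l1, params$l2))
  }
  if (params$m1 + params$m2 > 1) {
    violations <- c(violations,
                    sprintf("m1+m2>1 (m1 = %g, m2 = %g)", params$m1, params$m2))
  }
  structure(violations, class = "sosa_validation")
}

#' @rdname validate_parameters
#' @export
is_valid <- function(params) {
  length(validate_parameters(params)) == 0
}

#' @export
print.sosa_validation <- function(x, ...) {
  if (length(x) == 0) {
    cat("parameters valid\n")
  } else {
    cat("parameter violations:\n")
    for (v in x) cat(" -", v, "\n")
  }
  invisible(x)
}

#' @export
print.sosa_params <- function(x, ...) {
  cat("modified SOSa-SPSa parameters (", x$contact_scaling,
      "-dependent contact)\n", sep = "")
  r <- unlist(x[rate_names()])
  print(r)
  invisible(x)
}

stop_if_invalid <- function(params) {
  rep <- validate_parameters(params)
  if (length(rep) > 0) {
    stop("invalid parameters: ", paste(rep, collapse = "; "), call. = FALSE)
  }
  invisible(params)
}

#' Drop the optimist-pessimist interaction terms
#'
#' Projects a parameter set onto the original two-channel SOSa-SPSa model, in
#' which optimists and pessimists can only revert to susceptible and never
#' interact directly: `l1`, `l2`, `m1`, `m2` are set to zero, all other rates
#' kept. Under the returned parameters the right-hand side contains no O*P
#' coupling and decomposes into two independent SISa channels sharing the
#' susceptible pool.
#'
#' @param params a [model_parameters()] object.
#' @return A `sosa_params` object with all four interaction rates zero.
#' @export
reduce_to_original <- function(params) {
  stopifnot(inherits(params, "sosa_params"))
  params$l1 <- 0
  params$l2 <- 0
  params$m1 <- 0
  params$m2 <- 0
  params
}

#' Baseline parameter set estimated from the Framingham Heart Study
#'
#' The rate constants reported by Hill et al. (2010) from longitudinal
#' Framingham Heart Study (FHS) sentiment data, extended with the four
#' interaction rates, together with the canonical initial population split.
#' Shipped as the JSON fixture `hill2010_fhs.json` under `extdata`; this
#' helper loads it into R objects.
#'
#' @return A list with elements `params` (`sosa_params`), `initial` (named
#'   state vector `S`, `O`, `P`) and `N` (total crowd size, 1880).
#' @export
#' @examples
#' fx <- fhs_parameters()
#' fx$N
fhs_parameters <- function() {
  cfg <- load_config(fhs_config_path())
  list(params = cfg$params, initial = cfg$initial, N = cfg$N)
}

#' @rdname fhs_parameters
#' @export
fhs_config_path <- function() {
  system.file("extdata", "hill2010_fhs.json", package = "sosaspsa",
              mustWork = TRUE)
}
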