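#' Population state constructor
#'
#' A population state is a named numeric vector `c(S, O, P)` of susceptible,
#' optimistic and pessimistic counts. Counts are real-valued (the deterministic
#' model is a continuous approximation); only the stochastic simulator works
#' on integers.
#'
#' @param S,O,P nonnegative compartment counts.
#' @return Named numeric vector with elements `S`, `O`, `P`.
#' @export
population_state <- function(S, O, P) {
  st <- c(S = as.numeric(S), O = as.numeric(O), P = as.numeric(P))
  if (any(!is.finite(st)) || any(st < 0)) {
    stop("state components must be finite and nonnegative", call. = FALSE)
  }
  st
}

#' Express a state as compartment fractions
#'
#' @param state named state vector (`S`, `O`, `P`).
#' @param N total population size.
#' @return Named vector of fractions summing to `sum(state)/N`.
#' @export
state_fractions <- function(state, N) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  state[c("S", "O", "P")] / N
}

contact_factor <- function(params, N) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (params$contact_scaling == "frequency") 1 / N else 1
}

#' Right-hand side of the modified SOSa-SPSa system
#'
#' Time derivatives of the three compartments under the interaction-extended
#' model. With contact factor `c` (`1/N` for frequency-dependent transmission,
#' `1` for density-dependent):
#'
#' \deqn{dS/dt = g_O O + g_P P - (\alpha_O+\alpha_P) S
#'       - c(\beta_O O + \beta_P P) S + c(l_1+m_1) O P}
#' \deqn{dO/dt = -g_O O + \alpha_O S + c\,\beta_O O S - c(l_1+l_2-m_2) O P}
#' \deqn{dP/dt = -g_P P + \alpha_P S + c\,\beta_P P S - c(m_1+m_2-l_2) O P}
#'
#' The susceptible derivative is returned as `-(dO/dt + dP/dt)`, algebraically
#' identical to the first line, so the population is closed by construction:
#' the three components cancel to machine rounding (a final-summation ulp,
#' about 1e-14 relative, is all that remains).
#'
#' @param state named state vector (`S`, `O`, `P`).
#' @param params a [model_parameters()] object.
#' @param N total population size (> 0).
#' @return Named vector `c(dS_dt, dO_dt, dP_dt)`; components sum to 0 to
#'   machine precision.
#' @export
#' @examples
#' fx <- fhs_parameters()
#' modified_rhs(fx$initial, fx$params, fx$N)
modified_rhs <- function(state, params, N) {
  cc <- contact_factor(params, N)
  S <- state[["S"]]; O <- state[["O"]]; P <- state[["P"]]
  OP <- O * P
  dO <- -params$g_O * O + params$alpha_O * S + cc * params$beta_O * O * S -
    cc * (params$l1 + params$l2 - params$m2) * OP
  dP <- -params$g_P * P + params$alpha_P * S + cc * params$beta_P * P * S -
    cc * (params$m1 + params$m2 - params$l2) * OP
  c(dS_dt = -(dO + dP), dO_dt = dO, dP_dt = dP)
}

#' Right-hand side of the single-channel SISa model
#'
#' The susceptible-infected-susceptible model with spontaneous infection:
#' susceptibles become infected by contact at rate `beta` (scaled by the
#' contact convention) and spontaneously at rate `alpha`; the infected recover
#' at rate `g`.
#'
#' @param state named vector `c(S, I)` with `S + I = N`.
#' @param alpha spontaneous infection rate.
#' @param beta transmission rate per contact.
#' @param g recovery rate.
#' @param N total population size (> 0).
#' @param contact_scaling `"frequency"` or `"density"`.
#' @return Named vector `c(dS_dt, dI_dt)` summing to 0 to machine precision.
#' @export
sisa_rhs <- function(state, alpha, beta, g, N,
                     contact_scaling = c("frequency", "density")) {
  contact_scaling <- match.arg(contact_scaling)
  if (N <= 0) stop("N must be positive", call. = FALSE)
  cc <- if (contact_scaling == "frequency") 1 / N else 1
  S <- state[["S"]]; I <- state[["I"]]
  dI <- alpha * S + cc * beta * S * I - g * I
  c(dS_dt = -dI, dI_dt = dI)
}
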