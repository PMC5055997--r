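#' Integrate the modified SOSa-SPSa system
#'
#' Solves the three-compartment ODE system from an initial state on
#' `[0, t_end]` with `deSolve`'s adaptive `lsoda` integrator. Tight default
#' tolerances (relative 1e-10, absolute 1e-12*N) keep conservation of the
#' total meaningful along the trajectory; conservation and non-negativity are
#' asserted on the result rather than silently repaired.
#'
#' @param params a [model_parameters()] object (validated before use).
#' @param initial named state vector (`S`, `O`, `P`) summing to `N`.
#' @param N total population size.
#' @param t_end final time (abstract units), default 2000.
#' @param n_points number of saved points including t = 0.
#' @param rtol,atol integrator tolerances.
#' @return A `sosa_trajectory`: a data.frame with columns `t`, `S`, `O`, `P`
#'   and attributes `params` and `N`.
#' @export
#' @examples
#' fx <- fhs_parameters()
#' tr <- simulate_contagion(fx$params, fx$initial, fx$N, t_end = 50)
#' tail(tr, 1)
simulate_contagion <- function(params, initial, N, t_end = 2000,
                               n_points = 201, rtol = 1e-10,
                               atol = 1e-12 * N) {
  stop_if_invalid(params)
  check_state(initial, N)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  times <- seq(0, t_end, length.out = n_points)
  deriv <- function(t, y, p) {
    list(modified_rhs(y, params, N))
  }
  sol <- deSolve::ode(y = initial[c("S", "O", "P")], times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("integration failed near t = %g", sol[nrow(sol), "time"]),
         call. = FALSE)
  }
  traj <- data.frame(t = sol[, "time"], S = sol[, "S"], O = sol[, "O"],
                     P = sol[, "P"])
  check_trajectory(traj, N)
  structure(traj, params = params, N = N,
            class = c("sosa_trajectory", "data.frame"))
}

check_state <- function(state, N, tol = 1e-8) {
  if (!all(c("S", "O", "P") %in% names(state))) {
    stop("state must have named components S, O, P", call. = FALSE)
  }
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (abs(sum(state[c("S", "O", "P")]) - N) > tol * N) {
    stop(sprintf("state does not conserve the total: S+O+P = %.10g, N = %g",
                 sum(state[c("S", "O", "P")]), N), call. = FALSE)
  }
  invisible(state)
}

check_trajectory <- function(traj, N) {
  tot <- traj$S + traj$O + traj$P
  if (max(abs(tot - N)) > 1e-8 * N) {
    stop("conservation violated along trajectory", call. = FALSE)
  }
  if (min(traj$S, traj$O, traj$P) < -1e-9 * N) {
    stop("material negative compartment along trajectory", call. = FALSE)
  }
  invisible(traj)
}

#' Integrate until the system is numerically at steady state
#'
#' Runs [simulate_contagion()] and accepts the terminal state as an
#' equilibrium when the largest derivative component falls below
#' `tol` (default 1e-10*N); if not yet settled, the horizon is doubled once.
#'
#' @inheritParams simulate_contagion
#' @param tol steady-state criterion on `max(abs(rhs))`, in counts per time.
#' @return List with the final `state`, the achieved `max_deriv`, the reached
#'   `t_end`, and the full `trajectory`.
#' @export
integrate_to_equilibrium <- function(params, initial, N, t_end = 2000,
                                     n_points = 201, tol = 1e-10 * N) {
  for (horizon in c(t_end, 2 * t_end)) {
    traj <- simulate_contagion(params, initial, N, t_end = horizon,
                               n_points = n_points)
    fin <- unlist(traj[nrow(traj), c("S", "O", "P")])
    md <- max(abs(modified_rhs(fin, params, N)))
    if (md < tol) {
      return(list(state = fin, max_deriv = md, t_end = horizon,
                  trajectory = traj))
    }
  }
  stop(sprintf(paste0("no steady state within t = %g: max derivative ",
                      "component still %.3e"), 2 * t_end, md), call. = FALSE)
}

## Reduced 2-D system: unknowns (O, P), with S = N - O - P substituted so the
## conservation law holds by construction.
reduced_rhs <- function(op, params, N) {
  st <- c(S = N - op[1] - op[2], O = op[1], P = op[2])
  modified_rhs(st, params, N)[c("dO_dt", "dP_dt")]
}

## Analytic Jacobian of the reduced (O, P) system; dS/dO = dS/dP = -1.
reduced_jacobian <- function(op, params, N) {
  cc <- contact_factor(params, N)
  O <- op[1]; P <- op[2]; S <- N - O - P
  lOP <- params$l1 + params$l2 - params$m2
  mOP <- params$m1 + params$m2 - params$l2
  j11 <- -params$g_O - params$alpha_O + cc * params$beta_O * (S - O) -
    cc * lOP * P
  j12 <- -params$alpha_O - cc * params$beta_O * O - cc * lOP * O
  j21 <- -params$alpha_P - cc * params$beta_P * P - cc * mOP * P
  j22 <- -params$g_P - params$alpha_P + cc * params$beta_P * (S - P) -
    cc * mOP * O
  matrix(c(j11, j12, j21, j22), nrow = 2, byrow = TRUE,
         dimnames = list(c("dO_dt", "dP_dt"), c("O", "P")))
}

#' Locate an equilibrium by root finding
#'
#' Solves `dO/dt = dP/dt = 0` in the reduced two-unknown space (O, P with
#' S = N - O - P, so the total is conserved exactly by construction) starting
#' from a caller-supplied guess, using `pracma::fsolve` followed by Newton
#' polishing with the analytic Jacobian. The returned record carries the
#' steady-state identity residual (see [eq2_residual()]); eigenvalues are
#' populated by [assess_stability()].
#'
#' @param params a [model_parameters()] object.
#' @param guess named state vector summing to `N`; the root reached depends on
#'   it (only the root connected to the guess is reported).
#' @param N total population size.
#' @param tol residual tolerance on `max(abs(rhs))` in counts per time.
#' @return A `sosa_equilibrium` list: `state`, `residual_rhs`, `residual_eq2`,
#'   `eigenvalues` (NULL until assessed), `stable` (NA until assessed).
#' @export
#' @examples
#' fx <- fhs_parameters()
#' eq <- find_equilibrium(fx$params, fx$initial, fx$N)
#' state_fractions(eq$state, fx$N)
find_equilibrium <- function(params, guess, N, tol = 1e-10 * N) {
  stop_if_invalid(params)
  check_state(guess, N)
  op <- c(guess[["O"]], guess[["P"]])
  if (max(abs(reduced_rhs(op, params, N))) > tol) {
    # fsolve's own convergence warning is immaterial: the Newton polish below
    # re-checks the residual and errors out if the root is not reached
    sol <- tryCatch(
      suppressWarnings(
        pracma::fsolve(function(x) reduced_rhs(x, params, N), op,
                       maxiter = 200, tol = .Machine$double.eps^0.75)),
      error = function(e) NULL)
    if (!is.null(sol)) op <- as.numeric(sol$x)
  }
  # Newton polish: drives the residual to solver tolerance or reports failure
  for (i in seq_len(50)) {
    f <- reduced_rhs(op, params, N)
    if (max(abs(f)) <= tol) break
    step <- tryCatch(solve(reduced_jacobian(op, params, N), f),
                     error = function(e) NULL)
    if (is.null(step)) break
    op <- op - step
  }
  f <- reduced_rhs(op, params, N)
  if (max(abs(f)) > tol) {
    stop(sprintf(paste0("equilibrium search did not converge: residual %.3e ",
                        "at O = %.6g, P = %.6g"), max(abs(f)), op[1], op[2]),
         call. = FALSE)
  }
  state <- c(S = N - op[1] - op[2], O = op[1], P = op[2])
  if (min(state) < -1e-9 * N) {
    stop(sprintf(paste0("root has a materially negative component ",
                        "(S = %.4g, O = %.4g, P = %.4g); rejected"),
                 state[1], state[2], state[3]), call. = FALSE)
  }
  state <- pmax(state, 0)  # within the -1e-9*N tolerance band only
  res2 <- tryCatch(eq2_residual(state, params, N), error = function(e) NA_real_)
  structure(list(state = state,
                 residual_rhs = max(abs(modified_rhs(state, params, N))),
                 residual_eq2 = res2,
                 eigenvalues = NULL, stable = NA),
            class = "sosa_equilibrium")
}

#' Steady-state identity residual
#'
#' At an interior equilibrium both sentiment channels must express the same
#' susceptible count, giving the identity
#' \deqn{\frac{g_P P + c\,O P (m_1+m_2-l_2)}{\alpha_P + c\,\beta_P P}
#'     = \frac{g_O O + c\,O P (l_1+l_2-m_2)}{\alpha_O + c\,\beta_O O}}
#' (both sides equal S there). This function returns the absolute difference
#' of the two sides; it vanishes exactly when the state is an equilibrium of
#' the O/P subsystem. Defined only when both denominators are nonzero.
#'
#' @param state named state vector (`S`, `O`, `P`).
#' @param params a [model_parameters()] object.
#' @param N total population size.
#' @return Nonnegative scalar, in count units.
#' @export
eq2_residual <- function(state, params, N) {
  cc <- contact_factor(params, N)
  O <- state[["O"]]; P <- state[["P"]]
  den_P <- params$alpha_P + cc * params$beta_P * P
  den_O <- params$alpha_O + cc * params$beta_O * O
  if (den_P == 0 || den_O == 0) {
    stop("degenerate state: a channel denominator (alpha + c*beta*X) is zero",
         call. = FALSE)
  }
  lhs <- (params$g_P * P + cc * O * P * (params$m1 + params$m2 - params$l2)) /
    den_P
  rhs <- (params$g_O * O + cc * O * P * (params$l1 + params$l2 - params$m2)) /
    den_O
  abs(lhs - rhs)
}

#' Numerical linear stability of an equilibrium
#'
#' Evaluates the 2x2 Jacobian of the reduced (O, P) system at the equilibrium
#' by central finite differences (step 1e-6*N per coordinate) and reports its
#' eigenvalues; the equilibrium is flagged stable when all real parts are
#' negative. A numerical check in place of a full analytic stability
#' treatment, which the 12-parameter system does not readily admit.
#'
#' @param eq a `sosa_equilibrium` from [find_equilibrium()].
#' @param params a [model_parameters()] object.
#' @param N total population size.
#' @param h_rel finite-difference step relative to `N`.
#' @return The equilibrium record with `eigenvalues` and `stable` populated.
#' @export
assess_stability <- function(eq, params, N, h_rel = 1e-6) {
  stopifnot(inherits(eq, "sosa_equilibrium"))
  op <- c(eq$state[["O"]], eq$state[["P"]])
  J <- fd_jacobian(op, params, N, h = h_rel * N)
  ev <- eigen(J, only.values = TRUE)$values
  eq$eigenvalues <- ev
  eq$stable <- all(Re(ev) < 0)
  eq
}

fd_jacobian <- function(op, params, N, h) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (reduced_rhs(op + e, params, N) -
                 reduced_rhs(op - e, params, N)) / (2 * h)
  }
  dimnames(J) <- list(c("dO_dt", "dP_dt"), c("O", "P"))
  J
}

#' Probe for multiple equilibria from a simplex grid of starts
#'
#' Runs [find_equilibrium()] from a grid of starting compositions on the
#' (S, O, P) simplex and deduplicates the roots reached. An exploratory aid:
#' it probes, but cannot prove, uniqueness of the attractor.
#'
#' @param params a [model_parameters()] object.
#' @param N total population size.
#' @param n_starts approximate number of simplex grid starts (default 16).
#' @param dedup_tol roots closer than this (in counts) are merged.
#' @return List of distinct `sosa_equilibrium` records.
#' @export
multi_start_equilibria <- function(params, N, n_starts = 16,
                                   dedup_tol = 1e-6 * N) {
  k <- max(2, ceiling(sqrt(2 * n_starts)))
  fr <- seq(0.02, 0.98, length.out = k)
  roots <- list()
  for (o in fr) for (p in fr) {
    if (o + p >= 0.99) next
    st <- c(S = (1 - o - p) * N, O = o * N, P = p * N)
    eq <- tryCatch(find_equilibrium(params, st, N), error = function(e) NULL)
    if (is.null(eq)) next
    dup <- any(vapply(roots, function(r)
      max(abs(r$state - eq$state)) < dedup_tol, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- eq
  }
  roots
}

#' @export
print.sosa_equilibrium <- function(x, ...) {
  cat("equilibrium state (counts):\n")
  print(round(x$state, 6))
  cat(sprintf("max |rhs|: %.3e   steady-state identity residual: %.3e\n",
              x$residual_rhs, x$residual_eq2))
  if (!is.null(x$eigenvalues)) {
    cat("Jacobian eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
    cat("stable:", x$stable, "\n")
  }
  invisible(x)
}
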