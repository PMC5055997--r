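## Event-driven stochastic counterpart of the deterministic model.
## The ten transitions mirror the ten terms of the compartmental right-hand
## side, evaluated at the current integer state with frequency-dependent
## contact scaling.

event_kinds <- function() {
  c("S->O_spont", "S->O_contact", "O->S_recovery",
    "S->P_spont", "S->P_contact", "P->S_recovery",
    "O->S_meetP", "O->P_meetP", "P->S_meetO", "P->O_meetO")
}

## per-event state increments, rows (dS, dO, dP) per kind above
event_deltas <- function() {
  matrix(c(-1L,  1L,  0L,   # S->O spontaneous
           -1L,  1L,  0L,   # S->O by contact
            1L, -1L,  0L,   # O->S recovery
           -1L,  0L,  1L,   # S->P spontaneous
           -1L,  0L,  1L,   # S->P by contact
            1L,  0L, -1L,   # P->S recovery
            1L, -1L,  0L,   # O->S on meeting a pessimist (l1)
            0L, -1L,  1L,   # O->P on meeting a pessimist (l2)
            1L,  0L, -1L,   # P->S on meeting an optimist (m1)
            0L,  1L, -1L),  # P->O on meeting an optimist (m2)
         ncol = 3, byrow = TRUE,
         dimnames = list(event_kinds(), c("S", "O", "P")))
}

propensities <- function(S, O, P, params, cc) {
  OP <- O * P
  c(params$alpha_O * S,
    cc * params$beta_O * O * S,
    params$g_O * O,
    params$alpha_P * S,
    cc * params$beta_P * P * S,
    params$g_P * P,
    cc * params$l1 * OP,
    cc * params$l2 * OP,
    cc * params$m1 * OP,
    cc * params$m2 * OP)
}

#' Exact stochastic simulation of the sentiment-contagion transitions
#'
#' Gillespie direct method on an integer population: the ten transition
#' propensities are the ten terms of the compartmental right-hand side
#' evaluated at the current state (frequency-dependent contact scaling),
#' waiting times are exponential in the total propensity, and each event moves
#' exactly one individual. The run halts at `t_end`, or earlier if all
#' propensities vanish (absorption). A fixed seed reproduces the event
#' sequence bit for bit.
#'
#' @param params a [model_parameters()] object (frequency scaling is used for
#'   propensities regardless of the flag, matching the mean-field default).
#' @param initial integer state vector (`S`, `O`, `P`) summing to `N`.
#' @param N total population size.
#' @param t_end simulation horizon.
#' @param seed integer random seed.
#' @param record_events keep the full per-event log (set FALSE for large runs
#'   where only `t_grid` snapshots are needed).
#' @param t_grid optional time points at which to record the state (the state
#'   in force at each grid time, i.e. after the last event at or before it).
#' @return A `sosa_events` list: `events` (data.frame `t,event,S,O,P`, empty
#'   if `record_events = FALSE`), `final` state, `absorbed` flag, `seed`, and
#'   `grid_states` (data.frame `t,S,O,P`) when `t_grid` was given.
#' @export
#' @examples
#' fx <- fhs_parameters()
#' run <- gillespie_run(fx$params, round(fx$initial), fx$N, t_end = 1,
#'                      seed = 42)
#' head(run$events)
gillespie_run <- function(params, initial, N, t_end, seed,
                          record_events = TRUE, t_grid = NULL) {
  stop_if_invalid(params)
  st <- as.integer(round(initial[c("S", "O", "P")]))
  if (sum(st) != N) stop("initial integer state must sum to N", call. = FALSE)
  set.seed(as.integer(seed))
  cc <- 1 / N
  deltas <- event_deltas()
  # unpack rates once; the event loop is the hot path
  aO <- params$alpha_O; bO <- cc * params$beta_O; gO <- params$g_O
  aP <- params$alpha_P; bP <- cc * params$beta_P; gP <- params$g_P
  l1 <- cc * params$l1; l2 <- cc * params$l2
  m1 <- cc * params$m1; m2 <- cc * params$m2
  S <- st[1]; O <- st[2]; P <- st[3]
  t <- 0
  absorbed <- FALSE
  # event log buffers grow by doubling; n_ev tracks the fill level
  cap <- 1024L; n_ev <- 0L
  ev_t <- numeric(cap); ev_k <- integer(cap)
  ev_S <- integer(cap); ev_O <- integer(cap); ev_P <- integer(cap)
  grid_idx <- 1L
  n_grid <- length(t_grid)
  gr_S <- integer(n_grid); gr_O <- integer(n_grid); gr_P <- integer(n_grid)
  # record the state in force at every grid time strictly before tt
  record_grid_before <- function(tt) {
    while (grid_idx <= n_grid && t_grid[grid_idx] < tt) {
      gr_S[grid_idx] <<- S; gr_O[grid_idx] <<- O; gr_P[grid_idx] <<- P
      grid_idx <<- grid_idx + 1L
    }
  }
  repeat {
    OP <- O * P
    # cumulative propensities of the ten transitions, scalar for speed
    c1 <- aO * S
    c2 <- c1 + bO * O * S
    c3 <- c2 + gO * O
    c4 <- c3 + aP * S
    c5 <- c4 + bP * P * S
    c6 <- c5 + gP * P
    c7 <- c6 + l1 * OP
    c8 <- c7 + l2 * OP
    c9 <- c8 + m1 * OP
    a0 <- c9 + m2 * OP
    if (a0 <= 0) {
      absorbed <- TRUE
      break
    }
    t_next <- t + stats::rexp(1, a0)
    if (t_next > t_end) break
    if (n_grid) record_grid_before(t_next)
    # direct-method selection; equal cumulative bounds resolve to the lower
    # indexed event
    u <- stats::runif(1) * a0
    k <- if (u <= c1) 1L else if (u <= c2) 2L else if (u <= c3) 3L else
      if (u <= c4) 4L else if (u <= c5) 5L else if (u <= c6) 6L else
      if (u <= c7) 7L else if (u <= c8) 8L else if (u <= c9) 9L else 10L
    S <- S + deltas[k, 1L]; O <- O + deltas[k, 2L]; P <- P + deltas[k, 3L]
    t <- t_next
    if (record_events) {
      if (n_ev == cap) {
        cap <- 2L * cap
        length(ev_t) <- cap; length(ev_k) <- cap
        length(ev_S) <- cap; length(ev_O) <- cap; length(ev_P) <- cap
      }
      n_ev <- n_ev + 1L
      ev_t[n_ev] <- t; ev_k[n_ev] <- k
      ev_S[n_ev] <- S; ev_O[n_ev] <- O; ev_P[n_ev] <- P
    }
  }
  if (n_grid) {
    while (grid_idx <= n_grid) {
      gr_S[grid_idx] <- S; gr_O[grid_idx] <- O; gr_P[grid_idx] <- P
      grid_idx <- grid_idx + 1L
    }
  }
  keep <- seq_len(n_ev)
  out <- list(
    events = data.frame(t = ev_t[keep], event = event_kinds()[ev_k[keep]],
                        S = ev_S[keep], O = ev_O[keep], P = ev_P[keep],
                        stringsAsFactors = FALSE),
    final = c(S = S, O = O, P = P),
    absorbed = absorbed, seed = as.integer(seed), t_end = t_end, N = N)
  if (n_grid) {
    out$grid_states <- data.frame(t = t_grid, S = gr_S, O = gr_O, P = gr_P)
  }
  structure(out, class = "sosa_events")
}

#' Ensemble mean and standard error of the stochastic model
#'
#' Runs the event-driven simulator `n_runs` times with deterministic sub-seeds
#' (`seed + i` for run i) and returns the per-time-point mean and standard
#' error of each compartment. Used to verify that the deterministic system is
#' the mean-field limit of the stochastic one.
#'
#' @inheritParams gillespie_run
#' @param t_grid time points at which compartments are recorded.
#' @param n_runs number of independent runs (>= 2).
#' @return Data.frame `t, mean_S, se_S, mean_O, se_O, mean_P, se_P`.
#' @export
ensemble_mean <- function(params, initial, N, t_grid, n_runs, seed) {
  if (n_runs < 2) stop("n_runs must be at least 2", call. = FALSE)
  acc <- array(0, dim = c(length(t_grid), 3, n_runs))
  for (i in seq_len(n_runs)) {
    run <- gillespie_run(params, initial, N, t_end = max(t_grid),
                         seed = seed + i, record_events = FALSE,
                         t_grid = t_grid)
    acc[, , i] <- as.matrix(run$grid_states[, c("S", "O", "P")])
  }
  mn <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), stats::sd) / sqrt(n_runs)
  data.frame(t = t_grid,
             mean_S = mn[, 1], se_S = se[, 1],
             mean_O = mn[, 2], se_O = se[, 2],
             mean_P = mn[, 3], se_P = se[, 3])
}

#' Rescale an initial state to a different population size
#'
#' Proportional scaling followed by largest-remainder rounding, so the
#' rescaled integer state sums exactly to the new total.
#'
#' @param initial named state vector (`S`, `O`, `P`).
#' @param N_old,N_new current and target totals.
#' @return Integer named state summing to `N_new`.
#' @export
scale_initial_state <- function(initial, N_old, N_new) {
  x <- initial[c("S", "O", "P")] * N_new / N_old
  fl <- floor(x)
  shortfall <- as.integer(round(N_new - sum(fl)))
  if (shortfall > 0) {
    take <- order(x - fl, decreasing = TRUE)[seq_len(shortfall)]
    fl[take] <- fl[take] + 1
  }
  st <- as.integer(fl)
  names(st) <- c("S", "O", "P")
  st
}

#' @export
print.sosa_events <- function(x, ...) {
  cat(sprintf("stochastic run: N = %d, t_end = %g, seed = %d, %d events%s\n",
              x$N, x$t_end, x$seed, nrow(x$events),
              if (x$absorbed) " (absorbed)" else ""))
  cat("final state:\n")
  print(x$final)
  invisible(x)
}
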