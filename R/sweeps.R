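## Parameter-sweep experiments: how the equilibrium composition responds to
## the pessimist recovery rate, the optimist->pessimist interaction rates and
## the spontaneous pessimism rate. Each grid point is an independent
## equilibrium solve, warm-started from its neighbour for continuity.

sweep_point <- function(params, N, start) {
  eq <- tryCatch(find_equilibrium(params, start, N), error = function(e) NULL)
  if (is.null(eq)) {
    list(frac = c(S = NA_real_, O = NA_real_, P = NA_real_),
         converged = FALSE, state = start)
  } else {
    list(frac = state_fractions(eq$state, N), converged = TRUE,
         state = eq$state)
  }
}

new_sweep <- function(df, swept) {
  structure(df, swept = swept, class = c("sosa_sweep", "data.frame"))
}

#' Equilibrium response to the pessimist recovery rate
#'
#' Solves for the equilibrium composition across a grid of pessimist recovery
#' rates `g_P`, holding all other rates at their base values. Faster recovery
#' drains the pessimist compartment: the equilibrium pessimist share falls,
#' with diminishing returns at high recovery rates.
#'
#' @param params base [model_parameters()].
#' @param N total population size.
#' @param gP_grid strictly increasing grid of recovery rates (default
#'   0.05 to 0.50 in steps of 0.05).
#' @return A `sosa_sweep` data.frame with columns `g_P`, `frac_S`, `frac_O`,
#'   `frac_P`, `converged`.
#' @export
#' @examples
#' fx <- fhs_parameters()
#' sw <- sweep_gP(fx$params, fx$N, gP_grid = c(0.1, 0.13, 0.2))
#' sw
sweep_gP <- function(params, N, gP_grid = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(all(diff(gP_grid) > 0), all(gP_grid > 0))
  start <- find_equilibrium(params, fixture_like_start(N), N)$state
  rows <- vector("list", length(gP_grid))
  for (i in seq_along(gP_grid)) {
    p <- params
    p$g_P <- gP_grid[i]
    pt <- sweep_point(p, N, start)
    if (pt$converged) start <- pt$state
    rows[[i]] <- data.frame(g_P = gP_grid[i], frac_S = pt$frac[["S"]],
                            frac_O = pt$frac[["O"]], frac_P = pt$frac[["P"]],
                            converged = pt$converged)
  }
  new_sweep(do.call(rbind, rows), "g_P")
}

## neutral warm start: even three-way split
fixture_like_start <- function(N) {
  c(S = N / 3, O = N / 3, P = N / 3)
}

#' Equilibrium response to the optimist-meets-pessimist outcome rates
#'
#' Sweeps `l2` (optimist turns pessimistic on meeting a pessimist), optionally
#' crossed with `l1` (optimist reverts to susceptible instead), and records
#' the equilibrium composition for every admissible pair (`l1 + l2 <= 1`).
#' When the pessimistic outcome dominates the susceptible one (`l2 > l1`),
#' pessimism is self-reinforcing and the equilibrium pessimist share climbs
#' steeply.
#'
#' @param params base [model_parameters()].
#' @param N total population size.
#' @param l2_grid strictly increasing grid for `l2` (default 0 to 0.3 by
#'   0.03).
#' @param l1_grid optional strictly increasing grid for `l1`; by default `l1`
#'   is held at its base value.
#' @return A `sosa_sweep` data.frame with columns `l1`, `l2`, `frac_S`,
#'   `frac_O`, `frac_P`, `converged`. Inadmissible pairs are reported with
#'   `converged = NA`.
#' @export
sweep_l2_vs_l1 <- function(params, N, l2_grid = seq(0, 0.3, by = 0.03),
                           l1_grid = NULL) {
  stopifnot(all(diff(l2_grid) > 0))
  if (is.null(l1_grid)) l1_grid <- params$l1 else
    stopifnot(all(diff(l1_grid) > 0))
  base_start <- find_equilibrium(params, fixture_like_start(N), N)$state
  rows <- list()
  for (l1 in l1_grid) {
    start <- base_start
    for (l2 in l2_grid) {
      if (l1 + l2 > 1) {
        rows[[length(rows) + 1]] <- data.frame(
          l1 = l1, l2 = l2, frac_S = NA_real_, frac_O = NA_real_,
          frac_P = NA_real_, converged = NA)
        next
      }
      p <- params
      p$l1 <- l1
      p$l2 <- l2
      pt <- sweep_point(p, N, start)
      if (pt$converged) start <- pt$state
      rows[[length(rows) + 1]] <- data.frame(
        l1 = l1, l2 = l2, frac_S = pt$frac[["S"]], frac_O = pt$frac[["O"]],
        frac_P = pt$frac[["P"]], converged = pt$converged)
    }
  }
  new_sweep(do.call(rbind, rows), c("l1", "l2"))
}

#' Equilibrium response to spontaneous pessimism across interaction regimes
#'
#' Crosses a grid of spontaneous pessimism rates `alpha_P` with a set of
#' (`l2`, `m2`) interaction pairs. The equilibrium pessimist share grows with
#' `alpha_P` but saturates: successive increments at high `alpha_P` are
#' smaller than at low `alpha_P`. At fixed `alpha_P` the share rises with
#' `l2` and falls with `m2`.
#'
#' @param params base [model_parameters()].
#' @param N total population size.
#' @param alphaP_grid strictly increasing grid (default 0.01, 0.04, 0.07,
#'   0.1).
#' @param lm_pairs data.frame with columns `l2` and `m2`. The defaults run
#'   from the baseline pair (susceptible-reverting outcome dominant) into the
#'   pessimism-dominant regime `l2 >> m2`, where the self-reinforcing
#'   interaction makes the saturation in `alpha_P` pronounced.
#' @return A `sosa_sweep` data.frame with columns `alpha_P`, `l2`, `m2`,
#'   `frac_S`, `frac_O`, `frac_P`, `converged`.
#' @export
sweep_alphaP_by_lm <- function(params, N,
                               alphaP_grid = c(0.01, 0.04, 0.07, 0.1),
                               lm_pairs = data.frame(
                                 l2 = c(0.009, 0.15, 0.2),
                                 m2 = c(0.07, 0.07, 0.05))) {
  stopifnot(all(diff(alphaP_grid) > 0),
            all(c("l2", "m2") %in% names(lm_pairs)))
  base_start <- find_equilibrium(params, fixture_like_start(N), N)$state
  rows <- list()
  for (j in seq_len(nrow(lm_pairs))) {
    start <- base_start
    for (a in alphaP_grid) {
      p <- params
      p$alpha_P <- a
      p$l2 <- lm_pairs$l2[j]
      p$m2 <- lm_pairs$m2[j]
      if (!is_valid(p)) {
        rows[[length(rows) + 1]] <- data.frame(
          alpha_P = a, l2 = p$l2, m2 = p$m2, frac_S = NA_real_,
          frac_O = NA_real_, frac_P = NA_real_, converged = NA)
        next
      }
      pt <- sweep_point(p, N, start)
      if (pt$converged) start <- pt$state
      rows[[length(rows) + 1]] <- data.frame(
        alpha_P = a, l2 = p$l2, m2 = p$m2, frac_S = pt$frac[["S"]],
        frac_O = pt$frac[["O"]], frac_P = pt$frac[["P"]],
        converged = pt$converged)
    }
  }
  new_sweep(do.call(rbind, rows), c("alpha_P", "l2", "m2"))
}
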