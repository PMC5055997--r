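# Baseline parameter set and random-case generators shared across tests.

fx <- fhs_parameters()

# random admissible parameter set: rates uniform on [lo, hi], interaction
# rates rescaled if they breach the probability budgets
random_params <- function(lo = 0, hi = 0.3) {
  r <- stats::runif(10, lo, hi)
  names(r) <- c("alpha_O", "beta_O", "g_O", "alpha_P", "beta_P", "g_P",
                "l1", "l2", "m1", "m2")
  if (r["l1"] + r["l2"] > 1) r[c("l1", "l2")] <- r[c("l1", "l2")] / 2
  if (r["m1"] + r["m2"] > 1) r[c("m1", "m2")] <- r[c("m1", "m2")] / 2
  do.call(model_parameters, as.list(r))
}

# random interior state summing to N
random_state <- function(N) {
  w <- stats::runif(3, 0.05, 1)
  w <- w / sum(w) * N
  c(S = w[1], O = w[2], P = w[3])
}
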