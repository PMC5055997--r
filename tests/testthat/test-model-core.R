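test_that("parameter validation flags each violated constraint", {
  expect_length(validate_parameters(fx$params), 0)
  expect_true(is_valid(fx$params))

  p <- fx$params
  p$l1 <- 0.6
  p$l2 <- 0.5
  rep <- validate_parameters(p)
  expect_length(rep, 1)
  expect_match(rep[1], "l1\\+l2>1")

  p <- fx$params
  p$beta_O <- -0.1
  rep <- validate_parameters(p)
  expect_length(rep, 1)
  expect_match(rep[1], "negative rate")

  # violations accumulate rather than masking one another
  p$m1 <- 0.9
  p$m2 <- 0.4
  expect_length(validate_parameters(p), 2)
})

test_that("rhs at the baseline state matches a term-by-term hand evaluation", {
  d <- modified_rhs(fx$initial, fx$params, fx$N)
  # independent arithmetic oracle: the three formulas written out literally
  cc <- 1 / 1880
  oS <- 0.088 * 626 + 0.13 * 626 - (0.18 + 0.04) * 628 -
    cc * (0.02 * 626 + 0.04 * 626) * 628 + cc * (0.13 + 0.09) * 626 * 626
  oO <- -0.088 * 626 + 0.18 * 628 + cc * 0.02 * 626 * 628 -
    cc * (0.13 + 0.009 - 0.07) * 626 * 626
  oP <- -0.13 * 626 + 0.04 * 628 + cc * 0.04 * 626 * 628 -
    cc * (0.09 + 0.07 - 0.009) * 626 * 626
  expect_equal(d[["dO_dt"]], oO, tolerance = 1e-12)
  expect_equal(d[["dP_dt"]], oP, tolerance = 1e-12)
  expect_equal(d[["dS_dt"]], oS, tolerance = 1e-10)
  # frozen values of that oracle, and the qualitative directions: optimism
  # grows, pessimism shrinks, the susceptible pool initially rises
  expect_equal(d[["dO_dt"]], 47.75152978723404, tolerance = 1e-12)
  expect_equal(d[["dP_dt"]], -79.37072127659575, tolerance = 1e-12)
  expect_equal(d[["dS_dt"]], 31.61919148936172, tolerance = 1e-10)
  expect_gt(d[["dO_dt"]], 0)
  expect_lt(d[["dP_dt"]], 0)
  expect_gt(d[["dS_dt"]], 0)
})

test_that("derivatives conserve the population exactly for random inputs", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_params()
    N <- stats::runif(1, 100, 5000)
    st <- random_state(N)
    d <- modified_rhs(st, p, N)
    expect_lt(abs(sum(d)), 1e-12 * N)
  }
})

test_that("a contagion-free population is a fixed point", {
  p <- fx$params
  p$alpha_O <- 0
  p$alpha_P <- 0
  d <- modified_rhs(c(S = fx$N, O = 0, P = 0), p, fx$N)
  expect_identical(unname(d), c(0, 0, 0))
})

test_that("frequency scaling makes counts and fractions equivalent", {
  set.seed(12)
  for (i in 1:10) {
    p <- random_params()
    N <- stats::runif(1, 100, 5000)
    st <- random_state(N)
    d_counts <- modified_rhs(st, p, N)
    d_frac <- modified_rhs(st / N, p, 1)
    expect_equal(d_counts, d_frac * N, tolerance = 1e-12)
  }
})

test_that("density scaling keeps the bilinear terms on raw counts", {
  p <- fx$params
  p$contact_scaling <- "density"
  d_den <- modified_rhs(fx$initial, p, fx$N)
  d_frq <- modified_rhs(fx$initial, fx$params, fx$N)
  # the two conventions differ by a factor N on every bilinear term
  lin <- function(params) {
    with(params, c(dO = -g_O * 626 + alpha_O * 628,
                   dP = -g_P * 626 + alpha_P * 628))
  }
  bil_frq <- c(d_frq[["dO_dt"]], d_frq[["dP_dt"]]) - lin(fx$params)
  bil_den <- c(d_den[["dO_dt"]], d_den[["dP_dt"]]) - lin(p)
  expect_equal(bil_den, bil_frq * fx$N, tolerance = 1e-12)
})

test_that("single-channel SISa derivative behaves at its boundary states", {
  N <- 500
  expect_identical(unname(sisa_rhs(c(S = N, I = 0), alpha = 0, beta = 0.3,
                                   g = 0.1, N = N)), c(0, 0))
  d <- sisa_rhs(c(S = N, I = 0), alpha = 0.07, beta = 0.3, g = 0.1, N = N)
  expect_equal(d[["dI_dt"]], 0.07 * N)
  set.seed(13)
  for (i in 1:10) {
    I <- stats::runif(1, 0, N)
    d <- sisa_rhs(c(S = N - I, I = I), alpha = 0.1, beta = 0.2, g = 0.05,
                  N = N)
    expect_lt(abs(sum(d)), 1e-12 * N)
  }
})

test_that("dropping the interaction recovers two coupled SISa channels", {
  red <- reduce_to_original(fx$params)
  expect_identical(unlist(red[c("l1", "l2", "m1", "m2")], use.names = FALSE),
                   c(0, 0, 0, 0))
  # idempotent projection
  expect_identical(reduce_to_original(red), red)

  set.seed(14)
  for (i in 1:20) {
    N <- stats::runif(1, 100, 5000)
    st <- random_state(N)
    d <- modified_rhs(st, red, N)
    dO <- sisa_rhs(c(S = st[["S"]], I = st[["O"]]), red$alpha_O, red$beta_O,
                   red$g_O, N)
    dP <- sisa_rhs(c(S = st[["S"]], I = st[["P"]]), red$alpha_P, red$beta_P,
                   red$g_P, N)
    expect_equal(d[["dO_dt"]], dO[["dI_dt"]], tolerance = 1e-12)
    expect_equal(d[["dP_dt"]], dP[["dI_dt"]], tolerance = 1e-12)
    expect_equal(d[["dS_dt"]], dO[["dS_dt"]] + dP[["dS_dt"]],
                 tolerance = 1e-12)
  }
})

test_that("with the optimist channel silent the model collapses to SISa", {
  p <- reduce_to_original(fx$params)
  p$alpha_O <- 0
  p$beta_O <- 0
  p$g_O <- 0
  set.seed(15)
  for (i in 1:10) {
    N <- 1000
    P <- stats::runif(1, 0, N)
    st <- c(S = N - P, O = 0, P = P)
    d <- modified_rhs(st, p, N)
    ds <- sisa_rhs(c(S = N - P, I = P), p$alpha_P, p$beta_P, p$g_P, N)
    expect_equal(d[["dO_dt"]], 0)
    expect_equal(d[["dP_dt"]], ds[["dI_dt"]], tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(modified_rhs(fx$initial, fx$params, 0), "N must be positive")
  expect_error(sisa_rhs(c(S = 1, I = 0), 0.1, 0.1, 0.1, N = -5),
               "N must be positive")
  expect_error(population_state(-1, 2, 3), "nonnegative")
  expect_error(model_parameters(alpha_O = "a", beta_O = 1, g_O = 1,
                                alpha_P = 1, beta_P = 1, g_P = 1),
               "finite numeric")
})
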