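# Monte-Carlo fixation of a single mutant under the same binomial
# Wright-Fisher update the analytics describe (independent oracle)
wf_fix_mc <- function(r, N, n_rep, seed) {
  set.seed(seed)
  wins <- 0L
  for (i in seq_len(n_rep)) {
    k <- 1L
    while (k > 0L && k < N) {
      p <- k * r / (k * r + (N - k))
      k <- rbinom(1L, N, p)
    }
    if (k == N) wins <- wins + 1L
  }
  wins / n_rep
}

test_that("fixation probability: neutral value, limits and Monte-Carlo agreement", {
  for (N in c(2, 10, 50, 200)) expect_identical(fixation_probability(1, N), 1 / N)
  expect_gt(fixation_probability(100, 50), 0.98)
  expect_lt(fixation_probability(0.2, 50), 1e-6)
  # continuity around r = 1
  expect_lt(abs(fixation_probability(1 + 1e-9, 100) - 0.01), 1e-6)
  # monotone in r
  u <- fixation_probability(c(0.8, 1, 1.2, 2), 40)
  expect_true(all(diff(u) > 0))
  expect_error(fixation_probability(0, 10), "r must be")
  # Monte-Carlo cross-check on the implemented update process
  mc <- wf_fix_mc(1.3, 40, 4000, seed = 7)
  ex <- fixation_probability(1.3, 40)
  expect_lt(abs(mc - ex), 3 * sqrt(ex * (1 - ex) / 4000) + 0.005)
})

test_that("v1 is a probability with the right limits and monotonicity", {
  expect_equal(solve_v1(tunneling_params(50, 0, 1, 2)), 1)
  v <- vapply(c(1.5, 2, 5, 20), function(a)
    solve_v1(tunneling_params(50, 0.01, 1, a)), numeric(1))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) < 0))  # decreasing in a
  vmu <- vapply(c(0.001, 0.01, 0.05), function(mu)
    solve_v1(tunneling_params(50, mu, 1, 2)), numeric(1))
  expect_true(all(diff(vmu) < 0))  # decreasing in mu
})

test_that("tunneling rate obeys its factorized form and vanishes without mutation", {
  expect_equal(tunneling_rate(tunneling_params(50, 0, 0.9, 2)), 0)
  p <- tunneling_params(100, 0.005, 0.8, 3)
  res <- tunneling_result(p)
  # arithmetic cross-check of T = N mu (1 - U)(1 - v1) from the components
  expect_equal(res$T, p$N * p$mu * (1 - res$U_rx) * (1 - res$v1),
               tolerance = 1e-12)
  expect_equal(res$T, tunneling_rate(p), tolerance = 1e-12)
  expect_equal(unname(sequential_rates(p)), c(res$rate_S1, res$rate_S2),
               tolerance = 1e-12)
})

test_that("expected time reduces to the pure sequential form as T -> 0", {
  # algebraic limit of the printed expression
  et <- function(T, S1, S2) T / (T + S1)^2 + S1 * (S1 + S2 + T) / (S2 * (T + S1)^2)
  S1 <- 0.013; S2 <- 0.21
  expect_equal(et(0, S1, S2), 1 / S1 + 1 / S2, tolerance = 1e-12)
  # and the package value is exactly this expression on its own components
  p <- tunneling_params(60, 0.008, 1, 2.5)
  res <- tunneling_result(p)
  expect_equal(res$expected_time, et(res$T, res$rate_S1, res$rate_S2),
               tolerance = 1e-12)
})

test_that("waiting time shortens with a fitter final genotype and a fitter intermediate", {
  et_a <- vapply(c(1.5, 2, 4), function(a)
    expected_fixation_time(tunneling_params(100, 0.005, 1, a)), numeric(1))
  expect_true(all(diff(et_a) < 0))
  # neutral intermediate beats an inferior one, all else equal
  et_neutral <- expected_fixation_time(tunneling_params(200, 0.001, 1, 2))
  et_inferior <- expected_fixation_time(tunneling_params(200, 0.001, 0.6, 2))
  expect_lt(et_neutral, et_inferior)
})

test_that("analytic waiting time tracks the brute-force two-step process", {
  for (case in list(c(10, 0.01, 0.5, 2), c(10, 0.01, 1, 5))) {
    Et <- expected_fixation_time(tunneling_params(case[1], case[2], case[3], case[4]))
    sim <- simulate_two_step(case[1], case[2], case[3], case[4], n_rep = 4000,
                             max_generations = 1e6, seed = 99)
    expect_lt(abs(Et / mean(sim$seeding, na.rm = TRUE) - 1), 0.1)
  }
  # determinism of the oracle itself
  a <- simulate_two_step(10, 0.01, 1, 2, n_rep = 50, seed = 3)
  b <- simulate_two_step(10, 0.01, 1, 2, n_rep = 50, seed = 3)
  expect_identical(a, b)
})

test_that("outcome sets: point masses choose deterministically, symmetry splits evenly", {
  # deterministic comparison: neutral path always wins
  pred <- predict_outcome_sets(1, 0.5, 2, n_sets = 40, set_size = 10,
                               N = 50, mu = 0.01, seed = 1)
  expect_true(all(pred$neutral_counts == 10))
  expect_equal(unname(pred$count_interval), c(10, 10))
  expect_true(all(diff(unname(pred$wait_interval)) >= 0))
  # identical (continuous) sample pools for both intermediates: ~50/50
  set.seed(8)
  pool <- exp(rnorm(400, 0, 0.05))
  a_pool <- exp(rnorm(400, log(2), 0.05))
  pred2 <- predict_outcome_sets(pool, pool, a_pool, n_sets = 30, set_size = 20,
                                N = 50, mu = 0.01, seed = 2)
  frac <- mean(pred2$neutral_counts) / 20
  expect_lt(abs(frac - 0.5), 0.1)
})

test_that("outcome sets reject degenerate inputs and redraw non-positive samples", {
  expect_error(predict_outcome_sets(numeric(0), 1, 2), "non-empty")
  pred <- predict_outcome_sets(c(-1, 1), c(0.5), c(2), n_sets = 5,
                               set_size = 8, N = 20, mu = 0.01, seed = 3)
  expect_gt(pred$n_redrawn, 0)
  expect_true(all(pred$neutral_counts <= 8))
})
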