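test_that("single steps respect trivial dynamics and conservation", {
  set.seed(1)
  # no retention, deterministic inflow: next occupancy is always the arrival
  ch <- open_chain(matrix(0, 1, 1), quiet = TRUE)
  pr <- arrival_constant(2)
  for (n in c(0, 3, 10)) {
    expect_equal(step_chain(ch, pr, n)$n_next, 2)
  }
  # empty system with no arrivals stays empty
  fx <- fixture_two_source()
  zero <- arrival_constant(c(0, 0, 0))
  expect_equal(step_chain(fx$chain, zero, c(0, 0, 0))$n_next, c(0, 0, 0))
  expect_error(step_chain(fx$chain, zero, c(-1, 0, 0)), "nonnegative")
  expect_error(step_chain(fx$chain, zero, c(0.5, 0, 0)), "integer")
})

test_that("mean one-step outflow matches the escape probabilities", {
  # from N = (10, 10, 10), E[O] = 10/4 + 10/2 + 0 = 7.5
  fx <- fixture_two_source()
  zero <- arrival_constant(c(0, 0, 0))
  n <- c(10, 10, 10)
  set.seed(99)
  outs <- replicate(1e4, step_chain(fx$chain, zero, n)$outflow)
  # Var(O) = sum N_i e_i (1 - e_i) = 10*(3/16) + 10*(1/4)
  se <- sqrt((10 * 3 / 16 + 10 / 4) / 1e4)
  expect_lt(abs(mean(outs) - 7.5), 4 * se)
})

test_that("trajectories conserve particles at every step", {
  fx <- fixture_three_state(0.4, 0.3)
  traj <- simulate_chain(fx$chain, fx$protocol, steps = 500, seed = 5)
  N <- as.matrix(traj[, c("N1", "N2", "N3")])
  tot <- rowSums(N)
  expect_equal(tot[-1], tot[-length(tot)] - traj$outflow[-1] +
                 traj$inflow[-1])
  expect_true(all(N >= 0))
  expect_true(all(N == round(N)))
  # all-zero protocol from empty start stays identically zero
  zero <- simulate_chain(fx$chain, arrival_constant(c(0, 0, 0)),
                         steps = 50, seed = 1)
  expect_true(all(occupancy_matrix(zero) == 0))
})

test_that("same seed reproduces the trajectory exactly", {
  fx <- fixture_one_vertex(0.5, 0.5)
  t1 <- simulate_chain(fx$chain, fx$protocol, steps = 200, seed = 11)
  t2 <- simulate_chain(fx$chain, fx$protocol, steps = 200, seed = 11)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("one-vertex time average attains the stationary mean", {
  fx <- fixture_one_vertex(0.5, 0.5)
  traj <- simulate_chain(fx$chain, fx$protocol, steps = 2e5, seed = 3)
  X <- occupancy_matrix(traj)[traj$t > 1000, , drop = FALSE]
  be <- batch_estimate(X, function(m) mean(m[, 1]))
  expect_lt(abs(be$estimate - fx$closed$mu_bar), 3 * be$se)
})

test_that("replicate ensembles track the exact moment recursions", {
  ch <- random_open_chain(4, seed = 21)
  pr <- arrival_bernoulli(c(0.6, 0.1, 0.4, 0.8))
  R <- 2000L
  t_max <- 20L
  set.seed(77)
  runs <- lapply(seq_len(R), function(r) {
    simulate_chain(ch, pr, steps = t_max)
  })
  theory <- moment_recursion(ch, pr, t_max)
  for (t_check in c(1L, 5L, 20L)) {
    X <- t(vapply(runs, function(tr) occupancy_matrix(tr)[t_check + 1L, ],
                  numeric(4)))
    se_mu <- apply(X, 2, stats::sd) / sqrt(R)
    expect_true(all(abs(colMeans(X) - theory$mu[[t_check + 1L]]) <=
                      4 * se_mu + 1e-12))
    cv <- stats::cov(X)
    sig <- theory$sigma[[t_check + 1L]]
    for (i in 1:4) {
      for (j in i:4) {
        prods <- (X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))
        se_ij <- stats::sd(prods) / sqrt(R)
        expect_lt(abs(cv[i, j] - sig[i, j]), 4 * se_ij + 1e-12)
      }
    }
  }
})

test_that("empirical moments and lagged covariances behave as estimators", {
  fx <- fixture_one_vertex(0.5, 0.5)
  traj <- simulate_chain(fx$chain, fx$protocol, steps = 2e4, seed = 9)
  est <- empirical_moments(traj, burn_in = 1000)
  expect_equal(length(est$mu), 1)
  expect_equal(dim(est$sigma), c(1, 1))
  expect_gt(est$n_obs, 1.8e4)

  ctc <- empirical_two_time_cov(traj, max_lag = 3, burn_in = 1000)
  expect_equal(length(ctc), 4)
  # lag 0 is the ordinary sample covariance (up to the common-mean centering)
  expect_equal(ctc[["0"]][1, 1], est$sigma[1, 1], tolerance = 1e-3)

  # memoryless chain (Q = 0): occupancies are i.i.d. arrivals, so lagged
  # covariance is zero within Monte-Carlo error
  ch0 <- open_chain(matrix(0, 2, 2), quiet = TRUE)
  pr <- arrival_bernoulli(c(0.5, 0.3))
  tr0 <- simulate_chain(ch0, pr, steps = 2e4, seed = 13)
  c1 <- empirical_two_time_cov(tr0, max_lag = 1, burn_in = 100)[["1"]]
  n <- 2e4 - 100
  se <- sqrt(0.25 * 0.25 / n) # product of Bernoulli variances
  expect_true(all(abs(c1) < 4 * se + 1e-12))
})

test_that("constant trajectories have zero sample covariance", {
  ch <- open_chain(matrix(0, 1, 1), quiet = TRUE)
  traj <- simulate_chain(ch, arrival_constant(3), steps = 2000, seed = 1)
  est <- empirical_moments(traj, burn_in = 10)
  expect_equal(est$mu, 3)
  expect_equal(est$sigma[1, 1], 0)
})
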