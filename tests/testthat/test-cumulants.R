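test_that("the multinomial covariance matrix Lambda has its closed forms", {
  expect_equal(lambda_matrix(c(0, 0), matrix(0.2, 2, 2)), matrix(0, 2, 2))
  # scalar case: Lambda = mu q (1 - q)
  expect_equal(lambda_matrix(3, matrix(0.4, 1, 1)),
               matrix(3 * 0.4 * 0.6, 1, 1))
  # symmetric three-state chain at its stationary mean:
  # off-diagonal entries are -q^2 / (2 - 4q)
  q <- 0.3
  fx <- fixture_three_state(0.5, q)
  lb <- lambda_matrix(fx$closed$mu_bar, fx$chain$Q)
  expect_equal(lb[1, 2], -q^2 / (2 - 4 * q), tolerance = 1e-14)
  expect_equal(lb[2, 3], -q^2 / (2 - 4 * q), tolerance = 1e-14)
  expect_equal(lb, t(lb))
  ev <- eigen(lb, only.values = TRUE)$values
  expect_true(all(ev > -1e-12)) # positive semidefinite
})

test_that("mean recursion: affine update and fixed point", {
  Q <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  eps <- c(0.5, 0.2)
  expect_equal(mean_step(c(0, 0), eps, Q), eps)
  expect_equal(mean_step(c(1, 2), eps, matrix(0, 2, 2)), eps)
  # scalar fixed point mu = p / (1 - q)
  p <- 0.4
  q <- 0.7
  mu <- p / (1 - q)
  expect_equal(mean_step(mu, p, matrix(q, 1, 1)), mu)
})

test_that("variance recursion converges to the Stein solution", {
  Q <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  d <- diag(c(0.2, 0.1))
  expect_equal(var_step(matrix(0, 2, 2), d, c(0, 0), Q), d)
  expect_equal(var_step(diag(2), d, c(1, 1), matrix(0, 2, 2)), d)

  fx <- fixture_three_state(0.40, 0.45)
  mu_bar <- stationary_mean(fx$protocol, fx$chain)
  target <- stationary_variance(fx$protocol, Q = fx$chain)
  sig <- matrix(0, 3, 3)
  mu <- c(0, 0, 0)
  eps <- arrival_mean(fx$protocol)
  delta <- arrival_cov(fx$protocol)
  # rho = 0.9: the mean error decays like rho^t, so ~300 steps are needed
  # to push mu below 1e-12 (and sigma, converging at rho^(2t), follows)
  for (t in 1:300) {
    sig <- var_step(sig, delta, mu, fx$chain$Q)
    mu <- mean_step(mu, eps, fx$chain$Q)
  }
  expect_lt(max(abs(sig - target)), 1e-10)
  expect_lt(max(abs(mu - mu_bar)), 1e-12)
})

test_that("stationary mean solves mu (I - Q) = eps", {
  expect_equal(stationary_mean(0.5, matrix(0.5, 1, 1)), 1)
  fx <- fixture_three_state(0.2, 0.25)
  expect_equal(stationary_mean(fx$protocol, fx$chain), fx$closed$mu_bar)
  Q0 <- matrix(0, 2, 2)
  expect_equal(stationary_mean(c(0.3, 0.7), Q0), c(0.3, 0.7))
})

test_that("Stein solve, series form and fixed-point property agree", {
  # no retention: covariance is the arrival covariance
  d <- matrix(c(0.3, 0.05, 0.05, 0.2), 2, 2)
  expect_equal(stationary_variance(d, c(1, 1), matrix(0, 2, 2)), d)

  # scalar: (Delta + Lambda) / (1 - q^2) with Delta = p(1-p), Lambda = p q
  p <- 0.5
  q <- 0.5
  fx <- fixture_one_vertex(p, q)
  sg <- stationary_variance(fx$protocol, Q = fx$chain)
  expect_equal(sg[1, 1], (p * (1 - p) + p * q) / (1 - q^2))
  expect_equal(sg[1, 1], fx$closed$sigma_bar)

  for (seed in 1:4) {
    ch <- random_open_chain(2 + seed %% 3, seed + 60)
    pr <- random_protocol(ch$S, seed + 3)
    mu_bar <- stationary_mean(pr, ch)
    sg <- stationary_variance(pr, Q = ch)
    # series truncation agrees with the direct solve
    expect_lt(max(abs(stationary_variance_series(pr, Q = ch) - sg)), 1e-10)
    # both stationary maps leave their solutions fixed
    expect_lt(max(abs(mean_step(mu_bar, arrival_mean(pr), ch$Q) - mu_bar)),
              1e-12)
    expect_lt(max(abs(var_step(sg, arrival_cov(pr), mu_bar, ch$Q) - sg)),
              1e-12)
  }
})

test_that("product-Poisson arrivals give a diagonal stationary covariance", {
  for (seed in 1:4) {
    ch <- random_open_chain(2 + seed, seed + 80)
    lam <- stats::runif(ch$S, 0.2, 3)
    pr <- arrival_poisson(lam)
    mu_bar <- stationary_mean(pr, ch)
    sg <- stationary_variance(pr, Q = ch)
    expect_lt(max(abs(sg - diag(mu_bar))), 1e-12)
  }
})

test_that("spatial correlations are a proper correlation matrix", {
  expect_equal(space_correlations(diag(c(2, 3))), diag(2))
  fx <- fixture_three_state(0.7, 0.25)
  k <- space_correlations(stationary_variance(fx$protocol, Q = fx$chain))
  expect_equal(diag(k), rep(1, 3))
  expect_equal(k, t(k))
  expect_true(all(abs(k) <= 1 + 1e-12))
})

test_that("two-time covariance is Sigma Q^s with geometric decay", {
  fx <- fixture_one_vertex(0.5, 0.5)
  sg <- stationary_variance(fx$protocol, Q = fx$chain)
  expect_equal(two_time_cov(sg, fx$chain, 0), sg)
  for (s in 1:6) {
    expect_equal(two_time_cov(sg, fx$chain, s)[1, 1], sg[1, 1] * 0.5^s)
  }
  f3 <- fixture_three_state(0.4, 0.45)
  s3 <- stationary_variance(f3$protocol, Q = f3$chain)
  norms <- vapply(0:12, function(s) max(abs(two_time_cov(s3, f3$chain, s))),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[13] / norms[1], f3$chain$rho^10)
})

test_that("normalized time correlations start at kappa and decay", {
  f3 <- fixture_three_state(0.4, 0.45)
  sg <- stationary_variance(f3$protocol, Q = f3$chain)
  ct0 <- normalized_time_corr(sg, f3$chain, 0)
  expect_equal(ct0, space_correlations(sg))
  expect_equal(diag(ct0), rep(1, 3))
  ct20 <- normalized_time_corr(sg, f3$chain, 20)
  expect_lt(max(abs(ct20)), 0.15)
})

test_that("the closed-form powers of the symmetric three-state Q are exact", {
  q <- 0.3
  Q <- matrix(q, 3, 3) - diag(q, 3)
  expect_equal(three_state_power(q, 0), diag(3))
  expect_equal(three_state_power(q, 1), Q)
  expect_equal(three_state_power(q, 2), q^2 * (matrix(1, 3, 3) + diag(3)))
  for (k in c(3, 5, 11, 20)) {
    expect_lt(max(abs(three_state_power(q, k) - matrix_power(Q, k))), 1e-12)
  }
})

test_that("stationary_moments bundles tidy/glance/autoplot views", {
  f3 <- fixture_three_state(0.4, 0.45)
  m <- stationary_moments(f3$chain, f3$protocol, max_lag = 4)
  expect_s3_class(m, "chain_moments")
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(td$mean, m$mu_bar)
  gl <- glance(m)
  expect_equal(gl$total_mean, sum(m$mu_bar))
  expect_lt(gl$flux_gap, 1e-10)
  expect_equal(nrow(m$time_corr), 5 * 9)
  p <- autoplot(m, pairs = cbind(1, 1:2))
  expect_s3_class(p, "ggplot")
})
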