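test_that("Bernoulli-product protocol has product moments and m.g.f.", {
  p <- c(0.1, 0, 0.6)
  pr <- arrival_bernoulli(p)
  expect_equal(arrival_mean(pr), p)
  expect_equal(arrival_cov(pr), diag(p * (1 - p)))
  # one state: F(alpha) = 1 - p + p e^alpha
  pr1 <- arrival_bernoulli(0.3)
  a <- 0.7
  expect_equal(arrival_mgf(pr1, a), 1 - 0.3 + 0.3 * exp(a))
  # zero probabilities: degenerate at 0
  set.seed(1)
  expect_true(all(draw_arrivals(arrival_bernoulli(c(0, 0)), 100) == 0))
})

test_that("constant protocol is degenerate", {
  pr <- arrival_constant(c(2))
  set.seed(1)
  expect_true(all(draw_arrivals(pr, 50) == 2))
  expect_equal(arrival_cov(pr), matrix(0, 1, 1))
  expect_equal(arrival_mgf(pr, 0.3), exp(2 * 0.3))
  # zero arrivals: closed chain
  expect_equal(arrival_mean(arrival_constant(c(0, 0))), c(0, 0))
  expect_error(arrival_constant(c(1.5)), "integer")
})

test_that("Poisson-product protocol has mean equal to variance", {
  lam <- c(1, 2)
  pr <- arrival_poisson(lam)
  expect_equal(arrival_mean(pr), lam)
  expect_equal(arrival_cov(pr), diag(lam))
  expect_equal(arrival_mean(arrival_poisson(c(0, 0))), c(0, 0))
  set.seed(42)
  J <- draw_arrivals(pr, 1e5)
  se <- sqrt(lam / 1e5)
  expect_true(all(abs(colMeans(J) - lam) < 4 * se))
})

test_that("coupled-Bernoulli arrivals have flat mean and tunable coupling", {
  for (p in c(0, 0.25, 0.5, 0.9, 1)) {
    pr <- arrival_coupled_bernoulli(p)
    expect_equal(arrival_mean(pr), rep(1 / 2, 3))
    # Cov(J1, J2) = (2p - 1)/4; J3 independent
    expect_equal(arrival_cov(pr)[1, 2], (2 * p - 1) / 4)
    expect_equal(arrival_cov(pr)[1, 3], 0)
    expect_equal(diag(arrival_cov(pr)), rep(1 / 4, 3))
  }
  expect_equal(arrival_cov(arrival_coupled_bernoulli(0.5))[1, 2], 0)
  expect_equal(arrival_cov(arrival_coupled_bernoulli(1))[1, 2], 1 / 4)
  expect_error(arrival_coupled_bernoulli(1.2))
})

test_that("joint pmf protocol reproduces enumerated moments", {
  # point mass
  pr <- arrival_pmf(matrix(c(0, 0), 1, 2), 1)
  expect_equal(arrival_mean(pr), c(0, 0))
  expect_equal(arrival_cov(pr), matrix(0, 2, 2))
  # two-row Bernoulli(1/2)
  pr2 <- arrival_pmf(matrix(c(1, 0), 2, 1), c(0.5, 0.5))
  expect_equal(arrival_mean(pr2), 0.5)
  expect_equal(arrival_cov(pr2)[1, 1], 0.25)
  # manual coupled-Bernoulli table matches the built-in constructor
  p <- 0.3
  tbl <- expand.grid(j1 = 0:1, j2 = 0:1, j3 = 0:1)
  prob <- apply(tbl, 1, function(j) {
    f12 <- if (j[1] == j[2]) p / 2 else (1 - p) / 2
    f12 * 0.5
  })
  manual <- arrival_pmf(as.matrix(tbl), prob)
  builtin <- arrival_coupled_bernoulli(p)
  expect_equal(arrival_mean(manual), arrival_mean(builtin),
               tolerance = 1e-15)
  expect_equal(arrival_cov(manual), arrival_cov(builtin), tolerance = 1e-15)
  expect_error(arrival_pmf(matrix(1, 1, 1), 0.9), "sum to 1")
})

test_that("custom protocols support stateful (autocorrelated) samplers", {
  # sticky Bernoulli chain: repeat last arrival w.p. 0.9, redraw otherwise;
  # marginal is Bernoulli(1/2), but the sequence is autocorrelated
  make_sticky <- function() {
    last <- 0L
    function(n) {
      out <- matrix(0L, n, 1L)
      for (t in seq_len(n)) {
        if (stats::runif(1) > 0.9) last <<- stats::rbinom(1, 1, 0.5)
        out[t, 1L] <- last
      }
      out
    }
  }
  pr <- arrival_custom(1, mean = 0.5, cov = matrix(0.25, 1, 1),
                       sample = make_sticky())
  set.seed(4)
  J <- draw_arrivals(pr, 2e4)
  expect_gt(stats::cor(J[-1, 1], J[-nrow(J), 1]), 0.5) # visibly sticky
  expect_lt(abs(mean(J) - 0.5), 0.05)
  # the moment engines only need the marginal moments
  ch <- open_chain(0.5, quiet = TRUE)
  expect_equal(stationary_mean(pr, ch), 1)
  expect_error(arrival_mgf(pr, 0.2), "m.g.f")
})

test_that("samplers agree with exact moments and mgf differentiation", {
  protos <- list(
    bernoulli = arrival_bernoulli(c(0.2, 0.7)),
    poisson = arrival_poisson(c(0.5, 1.5)),
    coupled = arrival_coupled_bernoulli(0.8),
    pmf = arrival_pmf(rbind(c(0, 0), c(2, 1), c(1, 3)), c(0.5, 0.3, 0.2))
  )
  set.seed(7)
  for (pr in protos) {
    expect_equal(arrival_mgf(pr, numeric(pr$S)), 1)
    J <- draw_arrivals(pr, 1e5)
    se <- sqrt(diag(arrival_cov(pr)) / nrow(J))
    expect_true(all(abs(colMeans(J) - arrival_mean(pr)) <= 4 * se + 1e-12))
    # empirical covariance entries within 4 SE of exact
    cv <- stats::cov(J)
    for (i in seq_len(pr$S)) {
      for (j in seq_len(pr$S)) {
        prods <- (J[, i] - mean(J[, i])) * (J[, j] - mean(J[, j]))
        se_ij <- stats::sd(prods) / sqrt(nrow(J))
        expect_lt(abs(cv[i, j] - arrival_cov(pr)[i, j]), 4 * se_ij + 1e-12)
      }
    }
    # numerical cumulants of the mgf reproduce mean and covariance
    cum <- mgf_cumulants(pr$mgf, pr$S)
    expect_lt(max(abs(cum$mu - arrival_mean(pr))), 1e-6)
    expect_lt(max(abs(cum$sigma - arrival_cov(pr))), 1e-4)
  }
})
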