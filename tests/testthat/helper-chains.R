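# Shared generators and estimators for the suite.

# Random strictly sub-stochastic chain: rows rescaled to random sums below
# `max_row`, so rho < max_row < 1.
random_open_chain <- function(S, seed, max_row = 0.8) {
  set.seed(seed)
  Q <- matrix(stats::runif(S * S), S, S)
  Q <- Q / rowSums(Q) * stats::runif(S, 0.2, max_row)
  open_chain(Q, quiet = TRUE)
}

random_protocol <- function(S, seed) {
  set.seed(seed)
  switch(1L + seed %% 3L,
         arrival_bernoulli(stats::runif(S)),
         arrival_poisson(stats::runif(S, 0, 2)),
         arrival_constant(sample(0:2, S, replace = TRUE)))
}

# Batch-means standard error of a statistic of an autocorrelated series:
# f maps a sub-matrix (rows = time) to a scalar; returns the full-sample
# estimate and the SE across non-overlapping blocks.
batch_estimate <- function(X, f, n_blocks = 50L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  est <- f(X)
  id <- cut(seq_len(nrow(X)), n_blocks, labels = FALSE)
  per_block <- vapply(seq_len(n_blocks),
                      function(b) f(X[id == b, , drop = FALSE]),
                      numeric(1))
  list(estimate = est, se = stats::sd(per_block) / sqrt(n_blocks))
}

# Exact stationary pmf of the one-vertex chain as an independent oracle:
# direct convolution of Bernoulli(p q^r) factors down to parameter `cut`.
bernoulli_convolution_pmf <- function(p, q, n_max, cut = 1e-14) {
  pmf <- c(1, numeric(n_max))
  r <- 0L
  repeat {
    w <- p * q^r
    if (w < cut) break
    shifted <- c(0, pmf[seq_len(n_max)])
    pmf <- (1 - w) * pmf + w * shifted
    r <- r + 1L
  }
  pmf
}
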