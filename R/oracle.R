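#' Exact probability tables for tiny open chains
#'
#' For systems with few states and small occupancies, the occupancy
#' distribution can be evolved exactly by enumerating the transition kernel
#' `K(k, n) = P(J + R = n | N = k)`: the redistribution vector `R` is a sum
#' of independent per-state multinomials, and `J` is the arrival vector.
#' These tables serve as a ground-truth oracle for the simulator and both
#' moment engines.
#'
#' @name exact_oracle
#' @details A `pmf_table` is a list with `S`, `n_max` (per-state occupancy
#'   cap), `prob` (dense array of dimension `rep(n_max + 1, S)`, entry
#'   `[n_1 + 1, ..., n_S + 1]` holding `P(N = n)`), and `truncation_mass`
#'   (probability that has ever left the enumerated box; tracked, never
#'   renormalized away). Tables with `truncation_mass > 1e-8` should not be
#'   trusted for tight comparisons.
NULL

new_pmf_table <- function(S, n_max, prob, truncation_mass = 0) {
  structure(list(S = S, n_max = n_max, prob = prob,
                 truncation_mass = truncation_mass),
            class = "pmf_table")
}

#' @export
print.pmf_table <- function(x, ...) {
  cat("<pmf_table> ", x$S, " state(s), cap ", x$n_max,
      ", truncation mass ", format(x$truncation_mass, digits = 3),
      "\n", sep = "")
  invisible(x)
}

check_oracle_size <- function(S, n_max) {
  if ((n_max + 1)^S > 1e6) {
    stop("state box too large to enumerate: (n_max + 1)^S must be <= 1e6.",
         call. = FALSE)
  }
}

# All occupancy vectors of the box as a ((n_max+1)^S) x S matrix, in the
# array's linear order (first state fastest).
box_states <- function(S, n_max) {
  as.matrix(expand.grid(rep(list(0:n_max), S), KEEP.OUT.ATTRS = FALSE))
}

# Distribution of the internal redistribution vector R given occupancy k:
# convolution over source states of multinomial destination counts.
# Returned as list(values = matrix, prob = vector) with exact probabilities.
redistribution_support <- function(chain, k) {
  S <- chain$S
  dist <- list(values = matrix(0, 1L, S), prob = 1)
  for (i in seq_len(S)) {
    ki <- k[i]
    if (ki == 0) next
    zi <- c(chain$Q[i, ], chain$e[i])
    grid <- as.matrix(expand.grid(rep(list(0:ki), S),
                                  KEEP.OUT.ATTRS = FALSE))
    grid <- grid[rowSums(grid) <= ki, , drop = FALSE]
    pr <- apply(grid, 1L, function(m) {
      stats::dmultinom(c(m, ki - sum(m)), prob = zi)
    })
    keep <- pr > 0
    dist <- convolve_support(dist,
                             list(values = grid[keep, , drop = FALSE],
                                  prob = pr[keep]))
  }
  dist
}

# Convolution of two finite vector distributions by pairwise sums;
# duplicates aggregated.
convolve_support <- function(a, b) {
  na <- nrow(a$values)
  nb <- nrow(b$values)
  vals <- a$values[rep(seq_len(na), times = nb), , drop = FALSE] +
          b$values[rep(seq_len(nb), each = na), , drop = FALSE]
  pr <- a$prob[rep(seq_len(na), times = nb)] *
        b$prob[rep(seq_len(nb), each = na)]
  key <- apply(vals, 1L, paste, collapse = ",")
  agg <- rowsum(pr, key)
  uniq <- match(rownames(agg), key)
  list(values = vals[uniq, , drop = FALSE], prob = as.numeric(agg))
}

#' Exact one-step kernel from a given occupancy
#'
#' The distribution of the next occupancy `N' = J + R` given `N = k`,
#' truncated to the box `[0, n_max]^S`; outcome mass falling outside the box
#' is reported as `truncation_mass`.
#'
#' @param chain An `open_chain` with small `S`.
#' @param protocol An `arrival_protocol` with finite (or Poisson-truncated)
#'   support.
#' @param k Source occupancy vector within the box.
#' @param n_max Per-state occupancy cap.
#' @return A `pmf_table` over next occupancies.
#' @export
exact_kernel <- function(chain, protocol, k, n_max) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S)
  S <- chain$S
  check_oracle_size(S, n_max)
  k <- check_counts(k, "k")
  stopifnot(length(k) == S, all(k <= n_max))
  arr <- protocol_support(protocol)
  dist <- convolve_support(redistribution_support(chain, k),
                           list(values = arr$values, prob = arr$prob))
  prob <- array(0, dim = rep(n_max + 1L, S))
  leak <- arr$leak
  inside <- rowSums(dist$values > n_max) == 0L
  leak <- leak + sum(dist$prob[!inside])
  if (any(inside)) {
    idx <- as.integer(dist$values[inside, , drop = FALSE] %*%
                      (n_max + 1L)^(seq_len(S) - 1L)) + 1L
    tot <- rowsum(dist$prob[inside], idx)
    prob[as.integer(rownames(tot))] <- as.numeric(tot)
  }
  new_pmf_table(S, n_max, prob, leak)
}

#' Evolve an exact occupancy pmf
#'
#' Pushes a probability table forward `t_max` steps through the exact
#' kernel. Kernels are cached per source occupancy, so repeated steps are
#' cheap after the first sweep.
#'
#' @param chain An `open_chain`.
#' @param protocol An `arrival_protocol` with finite support.
#' @param pmf0 Initial condition: a `pmf_table`, or an occupancy vector for
#'   a point mass (default: empty system).
#' @param t_max Number of steps.
#' @param n_max Per-state cap (required if `pmf0` is a vector).
#' @return A `pmf_table` at time `t_max` with accumulated
#'   `truncation_mass`.
#' @export
evolve_pmf <- function(chain, protocol, pmf0 = NULL, t_max, n_max = NULL) {
  tab <- as_pmf_table(pmf0, chain$S, n_max)
  cache <- new.env(parent = emptyenv())
  for (t in seq_len(t_max)) {
    tab <- pmf_step(chain, protocol, tab, cache)
  }
  tab
}

as_pmf_table <- function(pmf0, S, n_max) {
  if (inherits(pmf0, "pmf_table")) return(pmf0)
  if (is.null(n_max)) stop("`n_max` required for a point-mass start.",
                           call. = FALSE)
  check_oracle_size(S, n_max)
  if (is.null(pmf0)) pmf0 <- numeric(S)
  pmf0 <- check_counts(pmf0, "pmf0")
  stopifnot(length(pmf0) == S, all(pmf0 <= n_max))
  prob <- array(0, dim = rep(n_max + 1L, S))
  prob[1L + sum(pmf0 * (n_max + 1L)^(seq_len(S) - 1L))] <- 1
  new_pmf_table(S, n_max, prob, 0)
}

pmf_step <- function(chain, protocol, tab, cache = NULL) {
  S <- tab$S
  n_max <- tab$n_max
  states <- box_states(S, n_max)
  new_prob <- array(0, dim = rep(n_max + 1L, S))
  leak <- tab$truncation_mass
  active <- which(tab$prob > 0)
  for (lin in active) {
    p <- tab$prob[lin]
    key <- as.character(lin)
    kern <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(kern)) {
      kern <- exact_kernel(chain, protocol, states[lin, ], n_max)
      if (!is.null(cache)) cache[[key]] <- kern
    }
    new_prob <- new_prob + p * kern$prob
    leak <- leak + p * kern$truncation_mass
  }
  new_pmf_table(S, n_max, new_prob, leak)
}

#' Stationary pmf by fixed-point iteration
#'
#' Iterates [evolve_pmf()] one step at a time until the total-variation
#' change falls below `tol`.
#'
#' @param chain An `open_chain`.
#' @param protocol An `arrival_protocol` with finite support.
#' @param n_max Per-state cap.
#' @param tol Total-variation convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `pmf_table` with attribute `"iterations"`.
#' @export
stationary_pmf <- function(chain, protocol, n_max, tol = 1e-12,
                           max_iter = 100000L) {
  tab <- as_pmf_table(NULL, chain$S, n_max)
  cache <- new.env(parent = emptyenv())
  for (it in seq_len(max_iter)) {
    nxt <- pmf_step(chain, protocol, tab, cache)
    tv <- sum(abs(nxt$prob - tab$prob)) / 2
    tab <- nxt
    if (tv < tol) {
      attr(tab, "iterations") <- it
      return(tab)
    }
  }
  stop("stationary pmf did not converge within max_iter iterations.",
       call. = FALSE)
}

#' Moments and m.g.f. of a pmf table
#'
#' `pmf_moments()` returns the exact mean vector and covariance matrix of
#' the tabulated distribution; `pmf_mgf()` evaluates its m.g.f. at `alpha`.
#' No renormalization is applied: if `truncation_mass` is material the
#' results are correspondingly biased, which is reported rather than hidden.
#'
#' @param table A `pmf_table`.
#' @param alpha Length-`S` numeric vector.
#' @return `pmf_moments()`: list with `mu`, `sigma`, `total_mass`;
#'   `pmf_mgf()`: scalar.
#' @export
pmf_moments <- function(table) {
  stopifnot(inherits(table, "pmf_table"))
  states <- box_states(table$S, table$n_max)
  p <- as.vector(table$prob)
  mu <- as.numeric(p %*% states)
  second <- t(states) %*% (states * p)
  sigma <- second - tcrossprod(mu)
  list(mu = mu, sigma = (sigma + t(sigma)) / 2, total_mass = sum(p))
}

#' @rdname pmf_moments
#' @export
pmf_mgf <- function(table, alpha) {
  stopifnot(inherits(table, "pmf_table"), length(alpha) == table$S)
  states <- box_states(table$S, table$n_max)
  sum(as.vector(table$prob) * exp(states %*% as.numeric(alpha)))
}

#' Exact two-time covariance by enumeration
#'
#' Brute-force `Cov(N^t, N^(t+s))` at stationarity: for every occupancy `n`
#' in the stationary table, a point mass at `n` is pushed `s` steps through
#' the exact kernel and the conditional mean accumulated. Only feasible for
#' tiny systems; confirms the product form `Sigma_bar Q^s` without using it.
#'
#' @param chain An `open_chain` (small `S`).
#' @param protocol An `arrival_protocol` with finite support.
#' @param s Nonnegative integer lag.
#' @param n_max Per-state cap.
#' @param stat Optional precomputed stationary `pmf_table` (saves repeated
#'   fixed-point iteration when sweeping over lags).
#' @return An `S x S` covariance matrix.
#' @export
two_time_joint_cov <- function(chain, protocol, s, n_max, stat = NULL) {
  stopifnot(s >= 0, s == round(s))
  if (is.null(stat)) stat <- stationary_pmf(chain, protocol, n_max)
  states <- box_states(stat$S, stat$n_max)
  p <- as.vector(stat$prob)
  mu <- as.numeric(p %*% states)
  if (s == 0) return(pmf_moments(stat)$sigma)
  cache <- new.env(parent = emptyenv())
  S <- stat$S
  second <- matrix(0, S, S)
  for (lin in which(p > 0)) {
    n0 <- states[lin, ]
    tab <- as_pmf_table(n0, S, n_max)
    for (step in seq_len(s)) tab <- pmf_step(chain, protocol, tab, cache)
    cond_mean <- as.numeric(as.vector(tab$prob) %*% states)
    second <- second + p[lin] * tcrossprod(n0, cond_mean)
  }
  second - tcrossprod(mu)
}

#' Tidy a pmf table
#'
#' @param x A `pmf_table`.
#' @param ... Unused.
#' @return A tibble with one row per occupancy vector of positive
#'   probability: columns `n1 ... nS` and `prob`.
#' @export
tidy.pmf_table <- function(x, ...) {
  states <- box_states(x$S, x$n_max)
  p <- as.vector(x$prob)
  keep <- p > 0
  out <- tibble::as_tibble(as.data.frame(states[keep, , drop = FALSE]))
  names(out) <- paste0("n", seq_len(x$S))
  out$prob <- p[keep]
  out
}
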