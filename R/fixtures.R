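#' Worked-example systems
#'
#' Constructors for the small open chains used throughout the tests and
#' documentation, each bundling a chain, an arrival protocol and the closed
#' forms known for it.
#'
#' @name fixtures
#' @return Each constructor returns a list of class `chain_fixture` with
#'   `name`, `params`, `chain`, `protocol` and `closed` (a list of
#'   closed-form quantities, possibly functions).
NULL

new_fixture <- function(name, params, chain, protocol, closed = list()) {
  structure(list(name = name, params = params, chain = chain,
                 protocol = protocol, closed = closed),
            class = "chain_fixture")
}

#' @export
print.chain_fixture <- function(x, ...) {
  cat("<chain_fixture> ", x$name, " (",
      paste(names(x$params), unlist(x$params), sep = " = ",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' One-vertex open chain
#'
#' A single state with retention probability `q` and Bernoulli(`p`)
#' arrivals. Everything is available in closed form: the stationary
#' occupancy is an infinite convolution of Bernoulli(`p q^r`) variables,
#' with mean `p / (1 - q)` and variance `p / (1 - q) - p^2 / (1 - q^2)`;
#' the stationary outflow has mean `p` and variance
#' `p - p^2 (1 - q)^2 / (1 - q^2)`.
#'
#' @param p Arrival probability in `[0, 1]`.
#' @param q Retention probability in `[0, 1)`.
#' @return A `chain_fixture`; `closed` holds `mu_bar`, `sigma_bar`,
#'   `out_mean`, `out_var`, `h_iterate(alpha, r)` and
#'   `stat_mgf_factor(alpha, r)`.
#' @export
fixture_one_vertex <- function(p, q) {
  stopifnot(p >= 0, p <= 1, q >= 0, q < 1)
  chain <- open_chain(matrix(q, 1, 1), quiet = TRUE)
  new_fixture(
    "one_vertex", list(p = p, q = q), chain, arrival_bernoulli(p),
    closed = list(
      mu_bar = p / (1 - q),
      sigma_bar = p / (1 - q) - p^2 / (1 - q^2),
      out_mean = p,
      out_var = p - p^2 * (1 - q)^2 / (1 - q^2),
      h_iterate = function(alpha, r) log(1 - q^r + q^r * exp(alpha)),
      stat_mgf_factor = function(alpha, r) {
        1 - p * q^r + p * q^r * exp(alpha)
      }
    )
  )
}

#' Ring open chain
#'
#' Random walkers on the cycle `Z/LZ` (states labelled `0 ... L-1`): from an
#' interior state `i != 0` a particle jumps to `i + 1 (mod L)` with
#' probability `q` and to `i - 1 (mod L)` with probability `1 - q`; from
#' state 0 it jumps to 1 with probability `a`, to `L - 1` with probability
#' `b`, and exits with probability `1 - a - b`. Bernoulli(`p`) arrivals enter
#' at state 0 only. The mean occupancy profile from an empty start is
#' `E[N^t] = sum_{r < t} p * Q^r[0, ]`.
#'
#' @param L Ring length, at least 2.
#' @param q Interior clockwise jump probability, in `(0, 1)`.
#' @param a,b Jump probabilities out of state 0, with `0 < a + b < 1`.
#' @param p Arrival probability at state 0.
#' @return A `chain_fixture`; `closed` holds `mean_profile(t)`.
#' @export
fixture_ring <- function(L, q, a, b, p) {
  stopifnot(L >= 2, q > 0, q < 1, a >= 0, b >= 0, a + b > 0, a + b < 1,
            p >= 0, p <= 1)
  Q <- matrix(0, L, L)
  idx <- function(i) (i %% L) + 1L # ring label -> row/column
  Q[idx(0), idx(1)] <- a
  Q[idx(0), idx(-1)] <- Q[idx(0), idx(-1)] + b
  if (L > 2) {
    for (i in seq_len(L - 1)) {
      Q[idx(i), idx(i + 1)] <- Q[idx(i), idx(i + 1)] + q
      Q[idx(i), idx(i - 1)] <- Q[idx(i), idx(i - 1)] + (1 - q)
    }
  } else {
    Q[2, 1] <- 1 # L = 2: both neighbours of state 1 are state 0
  }
  chain <- open_chain(Q, labels = as.character(0:(L - 1)), quiet = TRUE)
  new_fixture(
    "ring", list(L = L, q = q, a = a, b = b, p = p), chain,
    arrival_bernoulli(c(p, numeric(L - 1))),
    closed = list(
      mean_profile = function(t) {
        acc <- numeric(L)
        Qr <- diag(L)
        for (r in seq_len(t) - 1L) {
          acc <- acc + p * Qr[1L, ]
          Qr <- Qr %*% Q
        }
        acc
      }
    )
  )
}

#' Symmetric three-state chain with coupled arrivals
#'
#' Jump matrix `Q = q * (J - I)` (all off-diagonal entries `q`, zero
#' diagonal; `J` the all-ones matrix), requiring `0 < q < 1/2` so that the
#' spectral radius `2q` stays below 1. Arrivals follow
#' [arrival_coupled_bernoulli()] with coupling `p`. The stationary mean is
#' `1 / (2 - 4q)` in every state, and `Q^k` has the closed form of
#' [three_state_power()].
#'
#' @param p Arrival coupling parameter in `[0, 1]`.
#' @param q Off-diagonal jump probability in `(0, 1/2)`.
#' @return A `chain_fixture`; `closed` holds `mu_bar` and `Qk(k)`.
#' @export
fixture_three_state <- function(p, q) {
  stopifnot(p >= 0, p <= 1, q > 0, q < 0.5)
  Q <- matrix(q, 3, 3) - diag(q, 3)
  chain <- open_chain(Q, quiet = TRUE)
  new_fixture(
    "three_state", list(p = p, q = q), chain,
    arrival_coupled_bernoulli(p),
    closed = list(
      mu_bar = rep(1 / (2 - 4 * q), 3),
      Qk = function(k) three_state_power(q, k)
    )
  )
}

#' Closed-form powers of the symmetric three-state jump matrix
#'
#' `Q = q (J - I)` has eigenvalues `2q` (flat vector) and `-q` (twice), so
#' `Q^k = (q^k / 3) * [diag: 2^k + 2(-1)^k; off-diag: 2^k - (-1)^k]`.
#'
#' @param q Off-diagonal jump probability.
#' @param k Nonnegative integer power.
#' @return A symmetric `3 x 3` matrix; `k = 0` gives the identity.
#' @export
three_state_power <- function(q, k) {
  stopifnot(k >= 0, k == round(k))
  d <- (2^k + 2 * (-1)^k) / 3
  o <- (2^k - (-1)^k) / 3
  q^k * (matrix(o, 3, 3) + diag(d - o, 3))
}

#' Three-state chain with two arrival sources
#'
#' The jump matrix `rbind(c(0, 1/2, 1/4), c(1/4, 0, 1/4), c(1/2, 1/4, 1/4))`
#' with escape vector `(1/4, 1/2, 0)`: particles can leave from states 1 and
#' 2 but not 3. Arrivals are independent Bernoulli at states 1 and 3 with
#' probabilities `p1` and `p3` (none at state 2).
#'
#' @param p1,p3 Arrival probabilities at states 1 and 3.
#' @return A `chain_fixture`.
#' @export
fixture_two_source <- function(p1 = 0.1, p3 = 0.6) {
  Q <- rbind(c(0, 1 / 2, 1 / 4),
             c(1 / 4, 0, 1 / 4),
             c(1 / 2, 1 / 4, 1 / 4))
  chain <- open_chain(Q, quiet = TRUE)
  new_fixture(
    "two_source", list(p1 = p1, p3 = p3), chain,
    arrival_bernoulli(c(p1, 0, p3)),
    closed = list(e = c(1 / 4, 1 / 2, 0))
  )
}

#' List the bundled example systems
#'
#' @return A tibble naming each fixture constructor and its parameters.
#' @export
fixture_catalog <- function() {
  tibble::tibble(
    name = c("one_vertex", "ring", "three_state", "two_source"),
    constructor = c("fixture_one_vertex", "fixture_ring",
                    "fixture_three_state", "fixture_two_source"),
    parameters = c("p, q", "L, q, a, b, p", "p, q", "p1, p3")
  )
}
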