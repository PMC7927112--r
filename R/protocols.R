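#' Arrival protocols
#'
#' An arrival protocol is the law of the immigration vector `J^t`: the
#' numbers of particles arriving at each state per time step. Built-in
#' families are i.i.d. across time; each protocol carries its exact mean
#' vector, covariance matrix, moment generating function and a sampler.
#'
#' @name arrival_protocols
#' @details Protocols are lists of class `arrival_protocol` with fields
#'   `S` (dimension), `kind`, `params`, `mean` (length-`S` vector),
#'   `cov` (`S x S` matrix), `mgf` (function of a length-`S` vector `alpha`),
#'   and `sample` (function of `n` returning an `n x S` integer matrix,
#'   using the current RNG stream).
NULL

new_protocol <- function(S, kind, params, mean, cov, mgf, sample) {
  stopifnot(length(mean) == S, all(dim(cov) == c(S, S)))
  structure(
    list(S = S, kind = kind, params = params,
         mean = as.numeric(mean), cov = unname(cov),
         mgf = mgf, sample = sample),
    class = "arrival_protocol"
  )
}

#' @export
print.arrival_protocol <- function(x, ...) {
  cat("<arrival_protocol> kind:", x$kind, " states:", x$S, "\n")
  cat("mean arrivals/step:", paste(signif(x$mean, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic arrivals
#'
#' Exactly `j0[i]` particles arrive at state `i` every step.
#'
#' @param j0 Nonnegative integer vector of per-state arrival counts.
#' @return An `arrival_protocol`.
#' @export
arrival_constant <- function(j0) {
  j0 <- check_counts(j0, "j0")
  S <- length(j0)
  new_protocol(
    S, "constant", list(j0 = j0),
    mean = j0, cov = matrix(0, S, S),
    mgf = function(alpha) exp(sum(j0 * alpha)),
    sample = function(n) matrix(j0, n, S, byrow = TRUE)
  )
}

#' Independent Bernoulli arrivals
#'
#' At most one particle arrives at each state per step, independently across
#' states, with per-state probability `p[i]`.
#'
#' @param p Vector of probabilities in `[0, 1]`.
#' @return An `arrival_protocol` with mean `p` and covariance
#'   `diag(p * (1 - p))`.
#' @export
arrival_bernoulli <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0), all(p <= 1))
  S <- length(p)
  new_protocol(
    S, "bernoulli_product", list(p = p),
    mean = p, cov = diag(p * (1 - p), nrow = S),
    mgf = function(alpha) prod(1 - p + p * exp(alpha)),
    sample = function(n) {
      matrix(stats::rbinom(n * S, 1L, rep(p, each = n)), n, S)
    }
  )
}

#' Independent Poisson arrivals
#'
#' Poisson(`lambda[i]`) particles arrive at state `i` per step, independently
#' across states. Under this protocol the stationary occupancy is itself
#' product-Poisson with covariance `diag(mu_bar)`.
#'
#' @param lambda Nonnegative rate vector (particles/step).
#' @return An `arrival_protocol`.
#' @export
arrival_poisson <- function(lambda) {
  stopifnot(is.numeric(lambda), all(is.finite(lambda)), all(lambda >= 0))
  S <- length(lambda)
  new_protocol(
    S, "poisson_product", list(lambda = lambda),
    mean = lambda, cov = diag(lambda, nrow = S),
    mgf = function(alpha) exp(sum(lambda * (exp(alpha) - 1))),
    sample = function(n) {
      matrix(stats::rpois(n * S, rep(lambda, each = n)), n, S)
    }
  )
}

#' Arrivals from an explicit joint pmf table
#'
#' The arrival vector takes value `values[k, ]` with probability `prob[k]`.
#' Moments and the m.g.f. are computed by enumeration; sampling is
#' inverse-CDF over the rows.
#'
#' @param values Integer matrix, one support point per row (nonnegative).
#' @param prob Probability vector summing to 1 within `1e-12`.
#' @return An `arrival_protocol` of kind `"joint_pmf"`.
#' @export
arrival_pmf <- function(values, prob) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- unname(as.matrix(values))
  stopifnot(is.numeric(values), all(values >= 0),
            all(values == round(values)),
            length(prob) == nrow(values), all(prob >= 0))
  if (abs(sum(prob) - 1) > 1e-12) {
    stop("`prob` must sum to 1 (within 1e-12).", call. = FALSE)
  }
  S <- ncol(values)
  m <- as.numeric(prob %*% values)
  second <- t(values) %*% (values * prob)
  v <- second - tcrossprod(m)
  v <- (v + t(v)) / 2
  new_protocol(
    S, "joint_pmf", list(values = values, prob = prob),
    mean = m, cov = v,
    mgf = function(alpha) sum(prob * exp(values %*% alpha)),
    sample = function(n) {
      idx <- sample.int(nrow(values), n, replace = TRUE, prob = prob)
      values[idx, , drop = FALSE]
    }
  )
}

#' Coupled-Bernoulli arrivals on three states
#'
#' Three-state protocol in which states 1 and 2 receive a dependent pair of
#' Bernoulli(1/2) arrivals — both-or-neither with probability `p/2` each,
#' exactly-one with probability `(1 - p)/2` each — while state 3 receives an
#' independent Bernoulli(1/2) arrival. The parameter `p` tunes the
#' correlation of the (1, 2) pair: `Cov(J1, J2) = (2p - 1)/4`, zero at
#' `p = 1/2`. The marginal mean is `(1/2, 1/2, 1/2)` for every `p`.
#'
#' @param p Coupling parameter in `[0, 1]`.
#' @return An `arrival_protocol` (a `joint_pmf` over the 8-point support,
#'   kind `"coupled_bernoulli"`).
#' @export
arrival_coupled_bernoulli <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p), p >= 0, p <= 1)
  tbl <- coupled_bernoulli_table(p)
  proto <- arrival_pmf(tbl$values, tbl$prob)
  proto$kind <- "coupled_bernoulli"
  proto$params <- list(p = p)
  proto
}

# 8-point support: f12 on (j1, j2) times independent Bernoulli(1/2) on j3.
coupled_bernoulli_table <- function(p) {
  f12 <- rbind(
    c(1, 1, p / 2),
    c(0, 0, p / 2),
    c(1, 0, (1 - p) / 2),
    c(0, 1, (1 - p) / 2)
  )
  values <- NULL
  prob <- NULL
  for (k in seq_len(nrow(f12))) {
    for (j3 in 0:1) {
      values <- rbind(values, c(f12[k, 1:2], j3))
      prob <- c(prob, f12[k, 3] / 2)
    }
  }
  list(values = values, prob = prob)
}

#' Custom (possibly time-correlated) arrivals
#'
#' Escape hatch for arrival laws outside the built-in families: the caller
#' supplies the one-step marginal moments (and optionally the m.g.f.) plus a
#' sampler. The sampler may be a stateful closure, so autocorrelated
#' stationary arrival sequences can be simulated; note that the stationary
#' occupancy moments and the two-time covariance depend only on the one-step
#' marginal, so the analytic engines apply unchanged as long as `mean` and
#' `cov` describe that marginal.
#'
#' @param S Dimension.
#' @param mean Length-`S` marginal mean vector.
#' @param cov `S x S` marginal covariance matrix.
#' @param sample Function of `n` returning an `n x S` matrix of nonnegative
#'   integer arrival vectors for `n` consecutive steps.
#' @param mgf Optional m.g.f. of the marginal (required by the m.g.f.
#'   engine; the moment engines do not need it).
#' @return An `arrival_protocol` of kind `"custom"`.
#' @export
arrival_custom <- function(S, mean, cov, sample, mgf = NULL) {
  stopifnot(is.function(sample))
  if (is.null(mgf)) {
    mgf <- function(alpha) {
      stop("this custom protocol has no m.g.f.; supply `mgf` to use the ",
           "m.g.f. engine.", call. = FALSE)
    }
  }
  new_protocol(S, "custom", list(), mean, cov, mgf, sample)
}

#' Arrival moments and m.g.f.
#'
#' Accessors for the exact mean vector, covariance matrix and moment
#' generating function `F(alpha) = E[exp(J . alpha)]` of a protocol.
#'
#' @param protocol An `arrival_protocol`.
#' @param alpha Length-`S` numeric vector.
#' @return `arrival_mean()`: length-`S` vector; `arrival_cov()`: `S x S`
#'   matrix; `arrival_mgf()`: scalar, equal to 1 at `alpha = 0`.
#' @export
arrival_mean <- function(protocol) {
  stopifnot(inherits(protocol, "arrival_protocol"))
  protocol$mean
}

#' @rdname arrival_mean
#' @export
arrival_cov <- function(protocol) {
  stopifnot(inherits(protocol, "arrival_protocol"))
  protocol$cov
}

#' @rdname arrival_mean
#' @export
arrival_mgf <- function(protocol, alpha) {
  stopifnot(inherits(protocol, "arrival_protocol"),
            length(alpha) == protocol$S)
  protocol$mgf(as.numeric(alpha))
}

#' Draw arrival vectors
#'
#' @param protocol An `arrival_protocol`.
#' @param n Number of time steps to draw.
#' @return An `n x S` nonnegative integer matrix, one arrival vector per row,
#'   drawn from the current RNG stream (seed with [set.seed()]).
#' @export
draw_arrivals <- function(protocol, n) {
  stopifnot(inherits(protocol, "arrival_protocol"), n >= 0)
  out <- protocol$sample(as.integer(n))
  storage.mode(out) <- "double"
  out
}

# Finite support of a protocol as (values, prob); Poisson tails truncated at
# per-component mass `tol`. Used by the exact enumeration oracle.
protocol_support <- function(protocol, tol = 1e-14) {
  S <- protocol$S
  switch(
    protocol$kind,
    constant = list(values = matrix(protocol$params$j0, 1L, S),
                    prob = 1, leak = 0),
    joint_pmf = ,
    coupled_bernoulli = list(values = protocol$params$values,
                             prob = protocol$params$prob, leak = 0),
    bernoulli_product = {
      p <- protocol$params$p
      grid <- as.matrix(expand.grid(rep(list(0:1), S)))
      dimnames(grid) <- NULL
      prob <- apply(grid, 1L, function(j) prod(ifelse(j == 1, p, 1 - p)))
      keep <- prob > 0
      list(values = grid[keep, , drop = FALSE], prob = prob[keep], leak = 0)
    },
    poisson_product = {
      lam <- protocol$params$lambda
      caps <- vapply(lam, function(l) {
        if (l == 0) return(0L)
        cap <- stats::qpois(1 - tol, l) + 2L
        while (stats::ppois(cap, l, lower.tail = FALSE) > tol) cap <- cap + 1L
        cap
      }, integer(1))
      grid <- as.matrix(expand.grid(lapply(caps, function(k) 0:k)))
      dimnames(grid) <- NULL
      prob <- apply(grid, 1L, function(j) prod(stats::dpois(j, lam)))
      keep <- prob > 0
      list(values = grid[keep, , drop = FALSE], prob = prob[keep],
           leak = 1 - sum(prob))
    },
    stop("protocol kind '", protocol$kind, "' has no finite support.",
         call. = FALSE)
  )
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x))) {
    stop("`", name, "` must be a vector of nonnegative integers.",
         call. = FALSE)
  }
  as.numeric(x)
}
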