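#' Outflow transfer map
#'
#' The componentwise map `C_i(alpha) = log(1 - e_i + e_i * exp(alpha_i))`
#' that turns the occupancy m.g.f. into the m.g.f. of the departing counts:
#' the number of particles leaving state `i` is a binomial thinning
#' `Binom(N_i, e_i)` of the occupancy, and `R(alpha) = G(C(alpha))`.
#'
#' @param chain An `open_chain`.
#' @param alpha Length-`S` finite numeric vector.
#' @return A length-`S` vector with `c_map(chain, 0) = 0`.
#' @export
c_map <- function(chain, alpha) {
  stopifnot(inherits(chain, "open_chain"), length(alpha) == chain$S,
            all(is.finite(alpha)))
  log(1 - chain$e + chain$e * exp(as.numeric(alpha)))
}

#' M.g.f. of the outflow vector
#'
#' Composes the occupancy m.g.f. with the binomial-thinning transfer map:
#' at horizon `t` it is `G_t(C(alpha))`, at stationarity
#' `G_stat(C(alpha))`.
#'
#' @param chain An `open_chain`.
#' @param protocol A stationary `arrival_protocol`.
#' @param alpha Length-`S` numeric vector.
#' @param t Nonnegative integer horizon, or `Inf` (default) for the
#'   stationary m.g.f.
#' @param ... Passed on to [occupancy_mgf()] or [stationary_mgf()].
#' @return A scalar; equals 1 at `alpha = 0`.
#' @export
outflow_mgf <- function(chain, protocol, alpha, t = Inf, ...) {
  ca <- c_map(chain, alpha)
  if (is.infinite(t)) {
    as.numeric(stationary_mgf(chain, protocol, ca, ...))
  } else {
    occupancy_mgf(chain, protocol, ca, t, ...)
  }
}

#' Moments of the departing particle counts
#'
#' Given occupancy moments `(mu, sigma)` (time-dependent or stationary), the
#' per-state departures `U` have mean `mu * e` and covariance
#' `E sigma E + D` with `D = diag(mu * e * (1 - e))`; the total outflow `O`
#' has mean `sum(mu * e)` and variance `e sigma e' + mu (1 - e) e'`.
#'
#' @param mu Length-`S` mean occupancy.
#' @param sigma `S x S` occupancy covariance.
#' @param chain An `open_chain`.
#' @return A list of class `outflow_moments` with `mean_U`, `var_U`,
#'   `mean_O`, `var_O` and `D`.
#' @export
outflow_moments <- function(mu, sigma, chain) {
  stopifnot(inherits(chain, "open_chain"), length(mu) == chain$S,
            all(dim(sigma) == chain$S))
  e <- chain$e
  S <- chain$S
  D <- diag(as.numeric(mu) * e * (1 - e), nrow = S)
  var_U <- chain$E %*% sigma %*% chain$E + D
  structure(
    list(mean_U = as.numeric(mu) * e,
         var_U = (var_U + t(var_U)) / 2,
         mean_O = sum(as.numeric(mu) * e),
         var_O = as.numeric(e %*% sigma %*% e) + sum(mu * e * (1 - e)),
         D = D),
    class = "outflow_moments"
  )
}

#' @export
print.outflow_moments <- function(x, ...) {
  cat("<outflow_moments> mean total outflow/step:", signif(x$mean_O, 6),
      " variance:", signif(x$var_O, 6), "\n")
  invisible(x)
}

#' Stationary flux balance
#'
#' At stationarity the expected total outflow per step equals the expected
#' total inflow: `mu_bar %*% e == sum(eps)`. Returns both sides and their
#' gap, and errors if the identity fails beyond `tol` (which would indicate
#' an inconsistent chain/protocol pair or a non-stationary mean).
#'
#' @param eps Stationary arrival mean, or an `arrival_protocol`.
#' @param mu_bar Stationary mean occupancy; computed from `eps` if missing.
#' @param chain An `open_chain`.
#' @param tol Tolerance on the gap.
#' @return A list with `inflow`, `outflow` and `gap`.
#' @export
flux_balance <- function(eps, mu_bar = NULL, chain, tol = 1e-10) {
  if (inherits(eps, "arrival_protocol")) eps <- arrival_mean(eps)
  stopifnot(inherits(chain, "open_chain"), length(eps) == chain$S)
  if (is.null(mu_bar)) mu_bar <- stationary_mean(eps, chain)
  inflow <- sum(eps)
  outflow <- sum(as.numeric(mu_bar) * chain$e)
  gap <- abs(inflow - outflow)
  if (gap > tol * max(1, inflow)) {
    stop("stationary flux balance violated: inflow ", inflow,
         " vs outflow ", outflow, call. = FALSE)
  }
  list(inflow = inflow, outflow = outflow, gap = gap)
}
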