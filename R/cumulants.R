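#' Multinomial redistribution covariance contribution
#'
#' The matrix `Lambda[i, j] = sum_k mu[k] * (Q[k, i] * delta_ij -
#' Q[k, i] * Q[k, j])`, equivalently `diag(mu %*% Q) - t(Q) diag(mu) Q`:
#' the one-step covariance injected by multinomially redistributing a mean
#' occupancy `mu`. Symmetric positive semidefinite for `mu >= 0`.
#'
#' @param mu Length-`S` nonnegative mean occupancy vector.
#' @param Q Jump matrix (or an `open_chain`).
#' @return An `S x S` symmetric matrix.
#' @export
lambda_matrix <- function(mu, Q) {
  if (inherits(Q, "open_chain")) Q <- Q$Q
  mu <- as.numeric(mu)
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), length(mu) == nrow(Q),
            all(mu >= 0))
  S <- nrow(Q)
  L <- diag(as.numeric(mu %*% Q), nrow = S) - t(Q) %*% (mu * Q)
  (L + t(L)) / 2
}

#' One step of the cumulant recursions
#'
#' `mean_step()` advances the mean occupancy: `mu_{t+1} = eps + mu_t Q`.
#' `var_step()` advances the occupancy covariance:
#' `Sigma_{t+1} = Delta + Lambda(mu_t) + t(Q) Sigma_t Q`, where `Delta` is
#' the arrival covariance and `Lambda` the multinomial contribution. Both
#' accept time-dependent `eps`/`delta`.
#'
#' @param mu Length-`S` mean occupancy at time `t` (row-vector convention).
#' @param eps Length-`S` arrival mean at time `t`.
#' @param Q Jump matrix (or `open_chain`).
#' @param sigma `S x S` occupancy covariance at time `t`.
#' @param delta `S x S` arrival covariance at time `t`.
#' @return `mean_step()`: length-`S` vector; `var_step()`: `S x S` symmetric
#'   matrix.
#' @export
mean_step <- function(mu, eps, Q) {
  if (inherits(Q, "open_chain")) Q <- Q$Q
  stopifnot(length(mu) == nrow(Q), length(eps) == nrow(Q))
  as.numeric(eps) + as.numeric(mu %*% Q)
}

#' @rdname mean_step
#' @export
var_step <- function(sigma, delta, mu, Q) {
  if (inherits(Q, "open_chain")) Q <- Q$Q
  stopifnot(all(dim(sigma) == nrow(Q)), all(dim(delta) == nrow(Q)))
  out <- delta + lambda_matrix(mu, Q) + t(Q) %*% sigma %*% Q
  (out + t(out)) / 2
}

#' Time-dependent moments by recursion
#'
#' Runs the mean and covariance recursions for `t_max` steps from a given
#' initial condition (default: empty system), returning one row per time.
#'
#' @param chain An `open_chain`.
#' @param protocol A stationary `arrival_protocol`.
#' @param t_max Horizon.
#' @param mu0,sigma0 Initial mean and covariance (default zero).
#' @return A tibble with columns `t`, `mu` (list of vectors) and `sigma`
#'   (list of matrices), rows `t = 0 ... t_max`.
#' @export
moment_recursion <- function(chain, protocol, t_max, mu0 = NULL,
                             sigma0 = NULL) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S, t_max >= 0)
  S <- chain$S
  mu <- if (is.null(mu0)) numeric(S) else as.numeric(mu0)
  sigma <- if (is.null(sigma0)) matrix(0, S, S) else sigma0
  mus <- vector("list", t_max + 1L)
  sigmas <- vector("list", t_max + 1L)
  mus[[1L]] <- mu
  sigmas[[1L]] <- sigma
  eps <- arrival_mean(protocol)
  delta <- arrival_cov(protocol)
  for (t in seq_len(t_max)) {
    sigma <- var_step(sigma, delta, mu, chain$Q)
    mu <- mean_step(mu, eps, chain$Q)
    mus[[t + 1L]] <- mu
    sigmas[[t + 1L]] <- sigma
  }
  tibble::tibble(t = 0:t_max, mu = mus, sigma = sigmas)
}

#' Stationary mean occupancy
#'
#' Solves `mu_bar (I - Q) = eps`, i.e. `mu_bar = eps (I - Q)^{-1}`.
#'
#' @param eps Length-`S` stationary arrival mean, or an `arrival_protocol`.
#' @param Q Jump matrix or `open_chain`.
#' @return A length-`S` vector.
#' @export
stationary_mean <- function(eps, Q) {
  if (inherits(eps, "arrival_protocol")) eps <- arrival_mean(eps)
  if (inherits(Q, "open_chain")) Q <- Q$Q
  stopifnot(length(eps) == nrow(Q))
  as.numeric(solve(t(diag(nrow(Q)) - Q), as.numeric(eps)))
}

#' Stationary occupancy covariance (Stein equation)
#'
#' Solves the discrete Lyapunov (Stein) equation
#' `Sigma_bar = (Delta + Lambda_bar) + t(Q) Sigma_bar Q` by a vectorized
#' linear solve: `(I - t(Q) \%x\% t(Q)) vec(Sigma) = vec(Delta + Lambda_bar)`.
#' Equivalent to the series `sum_k (t(Q))^k (Delta + Lambda_bar) Q^k`, which
#' [stationary_variance_series()] computes as an independent cross-check.
#'
#' @param delta `S x S` stationary arrival covariance, or an
#'   `arrival_protocol` (from which both `delta` and, if `mu_bar` is missing,
#'   the stationary mean are taken).
#' @param mu_bar Stationary mean occupancy (from [stationary_mean()]).
#' @param Q Jump matrix or `open_chain`.
#' @return An `S x S` symmetric matrix.
#' @export
stationary_variance <- function(delta, mu_bar, Q) {
  if (inherits(Q, "open_chain")) Q <- Q$Q
  if (inherits(delta, "arrival_protocol")) {
    if (missing(mu_bar)) mu_bar <- stationary_mean(delta, Q)
    delta <- arrival_cov(delta)
  }
  S <- nrow(Q)
  stopifnot(all(dim(delta) == S), length(mu_bar) == S)
  if (spectral_radius(Q) >= 1) {
    stop("spectral radius must be below 1 for a stationary covariance.",
         call. = FALSE)
  }
  M <- delta + lambda_matrix(mu_bar, Q)
  A <- diag(S^2) - kronecker(t(Q), t(Q))
  sig <- matrix(solve(A, as.vector(M)), S, S)
  (sig + t(sig)) / 2
}

#' @rdname stationary_variance
#' @param tol Tail bound at which the series is truncated:
#'   `rho^(2K) / (1 - rho^2) * max(abs(M)) < tol`.
#' @export
stationary_variance_series <- function(delta, mu_bar, Q, tol = 1e-12) {
  if (inherits(Q, "open_chain")) Q <- Q$Q
  if (inherits(delta, "arrival_protocol")) {
    if (missing(mu_bar)) mu_bar <- stationary_mean(delta, Q)
    delta <- arrival_cov(delta)
  }
  S <- nrow(Q)
  M <- delta + lambda_matrix(mu_bar, Q)
  rho <- spectral_radius(Q)
  acc <- M
  term <- M
  k <- 0L
  norm_m <- max(abs(M))
  repeat {
    k <- k + 1L
    term <- t(Q) %*% term %*% Q
    acc <- acc + term
    if (rho > 0 && rho^(2 * k) / (1 - rho^2) * norm_m < tol) break
    if (rho == 0 || k > 1e6) break
  }
  (acc + t(acc)) / 2
}

#' Spatial correlations of the occupancy
#'
#' `kappa[i, j] = Sigma[i, j] / sqrt(Sigma[i, i] * Sigma[j, j])`, the
#' same-time correlation matrix of per-state particle numbers.
#'
#' @param sigma An `S x S` covariance matrix with positive diagonal.
#' @return An `S x S` correlation matrix with unit diagonal.
#' @export
space_correlations <- function(sigma) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma),
            all(diag(sigma) > 0))
  d <- sqrt(diag(sigma))
  out <- sigma / tcrossprod(d)
  diag(out) <- 1
  out
}

#' Two-time occupancy covariance
#'
#' `Cov(N^t, N^(t+s)) = Sigma_t Q^s`; with the stationary covariance it
#' decays geometrically in the lag `s` at rate `rho`, independently of any
#' autocorrelation in the arrival sequence.
#'
#' @param sigma Occupancy covariance at the earlier time (stationary or not).
#' @param Q Jump matrix or `open_chain`.
#' @param s Nonnegative integer lag; `s = 0` returns `sigma`.
#' @return An `S x S` matrix (not symmetric in general for `s > 0`).
#' @export
two_time_cov <- function(sigma, Q, s) {
  if (inherits(Q, "open_chain")) Q <- Q$Q
  stopifnot(all(dim(sigma) == nrow(Q)), s >= 0, s == round(s))
  sigma %*% matrix_power(Q, s)
}

#' Normalized time correlations
#'
#' `C_tilde(s)[i, j] = Cov(N_i^t, N_j^(t+s)) /
#' sqrt(Sigma_bar[i, i] * Sigma_bar[j, j])`; at `s = 0` this is the spatial
#' correlation matrix.
#'
#' @param sigma_bar Stationary occupancy covariance with positive diagonal.
#' @param Q Jump matrix or `open_chain`.
#' @param s Nonnegative integer lag.
#' @return An `S x S` matrix.
#' @export
normalized_time_corr <- function(sigma_bar, Q, s) {
  stopifnot(all(diag(sigma_bar) > 0))
  d <- sqrt(diag(sigma_bar))
  two_time_cov(sigma_bar, Q, s) / tcrossprod(d)
}

#' Stationary moment analysis of an open chain
#'
#' Convenience wrapper computing the stationary mean, covariance, spatial
#' correlations and outflow moments of a chain under a stationary arrival
#' protocol. Requires `rho < 1` and a time-invariant protocol (all built-in
#' families are).
#'
#' @param chain An `open_chain`.
#' @param protocol An `arrival_protocol`.
#' @param max_lag If positive, normalized time correlations are computed for
#'   lags `0 ... max_lag`.
#' @return An object of class `chain_moments`: a list with `mu_bar`,
#'   `sigma_bar`, `kappa`, `outflow` (an `outflow_moments` list),
#'   `flux` (stationary in/out rates), `time_corr` (tibble of normalized
#'   lag correlations, or `NULL`), plus `chain` and `protocol`.
#' @export
stationary_moments <- function(chain, protocol, max_lag = 0L) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S)
  mu_bar <- stationary_mean(protocol, chain)
  sigma_bar <- stationary_variance(arrival_cov(protocol), mu_bar, chain)
  kappa <- if (all(diag(sigma_bar) > 0)) space_correlations(sigma_bar)
           else NULL
  tc <- NULL
  if (max_lag > 0 && !is.null(kappa)) {
    tc <- time_corr_tibble(sigma_bar, chain$Q, max_lag)
  }
  structure(
    list(mu_bar = mu_bar, sigma_bar = sigma_bar, kappa = kappa,
         outflow = outflow_moments(mu_bar, sigma_bar, chain),
         flux = flux_balance(arrival_mean(protocol), mu_bar, chain),
         time_corr = tc, chain = chain, protocol = protocol),
    class = "chain_moments"
  )
}

time_corr_tibble <- function(sigma_bar, Q, max_lag) {
  S <- nrow(Q)
  purrr::map_dfr(0:max_lag, function(s) {
    ct <- normalized_time_corr(sigma_bar, Q, s)
    tibble::tibble(
      lag = s,
      i = rep(seq_len(S), times = S),
      j = rep(seq_len(S), each = S),
      corr = as.vector(ct)
    )
  })
}

#' @export
print.chain_moments <- function(x, ...) {
  cat("<chain_moments> stationary analysis,", x$chain$S, "state(s)\n")
  cat("mu_bar:   ", paste(signif(x$mu_bar, 5), collapse = ", "), "\n")
  cat("var diag: ", paste(signif(diag(x$sigma_bar), 5), collapse = ", "),
      "\n")
  cat("flux in = ", signif(x$flux$inflow, 6), ", flux out = ",
      signif(x$flux$outflow, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy stationary moments
#'
#' One row per state: stationary mean, variance, escape probability and the
#' mean and variance contribution of its outflow.
#'
#' @param x A `chain_moments` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.chain_moments <- function(x, ...) {
  tibble::tibble(
    state = x$chain$labels,
    mean = x$mu_bar,
    variance = diag(x$sigma_bar),
    escape = x$chain$e,
    outflow_mean = x$outflow$mean_U,
    outflow_variance = diag(x$outflow$var_U)
  )
}

#' @export
glance.chain_moments <- function(x, ...) {
  tibble::tibble(
    n_states = x$chain$S,
    spectral_radius = x$chain$rho,
    total_mean = sum(x$mu_bar),
    inflow_rate = x$flux$inflow,
    outflow_rate = x$flux$outflow,
    flux_gap = x$flux$gap
  )
}

#' Plot normalized time correlations
#'
#' Lag-correlation curves `C_tilde[i, j](s)` for the state pairs kept in the
#' `time_corr` component (run [stationary_moments()] with `max_lag > 0`).
#'
#' @param object A `chain_moments` object with a non-`NULL` `time_corr`.
#' @param pairs Optional 2-column matrix of (i, j) pairs to keep.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chain_moments <- function(object, pairs = NULL, ...) {
  tc <- object$time_corr
  if (is.null(tc)) {
    stop("no time correlations stored; rerun stationary_moments() with ",
         "max_lag > 0.", call. = FALSE)
  }
  if (!is.null(pairs)) {
    keep <- paste(tc$i, tc$j) %in% paste(pairs[, 1], pairs[, 2])
    tc <- tc[keep, ]
  }
  tc$pair <- paste0("(", tc$i, ",", tc$j, ")")
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$lag, y = .data$corr,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag s", y = "normalized correlation")
}
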