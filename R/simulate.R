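#' One step of the open-chain dynamics
#'
#' Each of the `N[i]` particles at state `i` independently chooses among the
#' `S` internal destinations and the exit, with probabilities
#' `(Q[i, 1], ..., Q[i, S], e[i])`, so the per-state destination counts are
#' multinomial. The next occupancy is the redistributed counts plus a fresh
#' arrival vector. Particle conservation —
#' `sum(N_next) = sum(N) - outflow + inflow` — holds exactly per realization
#' and is asserted.
#'
#' @param chain An `open_chain`.
#' @param protocol An `arrival_protocol` with matching dimension.
#' @param n Current occupancy: nonnegative integer vector of length `S`.
#' @return A list with `n_next` (next occupancy), `outflow` (total departures
#'   this step) and `arrivals` (the arrival vector drawn).
#' @export
step_chain <- function(chain, protocol, n) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S)
  n <- check_counts(n, "n")
  if (length(n) != chain$S) stop("`n` must have length S.", call. = FALSE)
  j <- as.numeric(draw_arrivals(protocol, 1L))
  zi <- cbind(chain$Q, chain$e)
  r <- numeric(chain$S)
  out <- 0
  for (i in seq_len(chain$S)) {
    if (n[i] > 0) {
      a <- stats::rmultinom(1L, n[i], zi[i, ])[, 1L]
      r <- r + a[seq_len(chain$S)]
      out <- out + a[chain$S + 1L]
    }
  }
  n_next <- j + r
  stopifnot(sum(n_next) == sum(n) - out + sum(j))
  list(n_next = n_next, outflow = out, arrivals = j)
}

#' Simulate an open Markov chain trajectory
#'
#' Iterates the multinomial-redistribution dynamics for `steps` steps from
#' the initial occupancy `n0`, recording occupancies, arrivals and
#' departures. Per-step particle conservation is asserted on every step.
#'
#' @param chain An `open_chain`.
#' @param protocol An `arrival_protocol`.
#' @param n0 Initial occupancy vector (default all zeros).
#' @param steps Number of steps (`T >= 1`).
#' @param seed Optional integer seed, recorded in the result.
#' @return A tibble of class `chain_trajectory` with one row per time
#'   `t = 0, ..., T`: occupancy columns `N1 ... NS`, plus `inflow` and
#'   `outflow` giving the totals of the step that *produced* row `t` (`NA`
#'   at `t = 0`). Arrival vectors are kept in the attribute `arrivals`
#'   (`T x S`); `chain`, `protocol` and `seed` are attached as attributes.
#' @details Occupancies are stored as doubles holding exact integers; the
#'   simulation errors if any count exceeds `2^53`, beyond which doubles can
#'   no longer represent counts exactly.
#' @export
simulate_chain <- function(chain, protocol, n0 = NULL, steps, seed = NULL) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S, steps >= 1)
  S <- chain$S
  if (is.null(n0)) n0 <- numeric(S)
  n0 <- check_counts(n0, "n0")
  stopifnot(length(n0) == S)
  if (!is.null(seed)) set.seed(seed)
  steps <- as.integer(steps)

  # i.i.d. protocols: pre-draw the whole arrival matrix in one call
  J <- draw_arrivals(protocol, steps)
  zi <- cbind(chain$Q, chain$e)
  N <- matrix(0, steps + 1L, S)
  N[1L, ] <- n0
  out_tot <- numeric(steps)
  n <- n0
  for (t in seq_len(steps)) {
    r <- numeric(S)
    out <- 0
    for (i in seq_len(S)) {
      ni <- n[i]
      if (ni > 0) {
        a <- stats::rmultinom(1L, ni, zi[i, ])[, 1L]
        r <- r + a[seq_len(S)]
        out <- out + a[S + 1L]
      }
    }
    n_new <- J[t, ] + r
    if (sum(n_new) != sum(n) - out + sum(J[t, ])) {
      stop("particle conservation violated at step ", t, call. = FALSE)
    }
    if (any(n_new > 2^53)) {
      stop("occupancy exceeds 2^53; counts no longer exact.", call. = FALSE)
    }
    N[t + 1L, ] <- n_new
    out_tot[t] <- out
    n <- n_new
  }

  traj <- tibble::as_tibble(as.data.frame(N))
  names(traj) <- paste0("N", seq_len(S))
  traj <- dplyr::mutate(
    traj,
    t = 0:steps,
    inflow = c(NA_real_, rowSums(J)),
    outflow = c(NA_real_, out_tot),
    .before = 1L
  )
  structure(traj,
            class = c("chain_trajectory", class(traj)),
            chain = chain, protocol = protocol, seed = seed,
            arrivals = J)
}

occupancy_matrix <- function(trajectory) {
  stopifnot(inherits(trajectory, "chain_trajectory"))
  as.matrix(trajectory[, grep("^N[0-9]+$", names(trajectory)), drop = FALSE])
}

#' Default burn-in for stationary estimates
#'
#' `max(1000, ceiling(50 / (1 - rho)))` steps: the occupancy process relaxes
#' geometrically at rate `rho`, so 50 relaxation times comfortably erases the
#' initial condition.
#'
#' @param chain An `open_chain`.
#' @return An integer number of steps.
#' @export
default_burn_in <- function(chain) {
  stopifnot(inherits(chain, "open_chain"))
  max(1000L, as.integer(ceiling(50 / (1 - chain$rho))))
}

#' Empirical occupancy moments
#'
#' Sample mean vector and sample covariance matrix (denominator `n - 1`) of
#' the occupancy rows of one or more trajectories. For a single long run the
#' rows after `burn_in` are treated as stationary draws; for a list of
#' replicate trajectories the occupancy at time `at` is used across
#' replicates.
#'
#' @param trajectories A `chain_trajectory` or a list of them.
#' @param burn_in Rows with `t <= burn_in` are dropped (single-trajectory
#'   mode). Defaults to [default_burn_in()] of the attached chain.
#' @param at Time index at which to read replicates (replicate mode).
#' @return A list with `mu` (mean vector), `sigma` (covariance matrix),
#'   `se_mu` (naive i.i.d. standard errors of the mean) and `n_obs`.
#' @export
empirical_moments <- function(trajectories, burn_in = NULL, at = NULL) {
  if (inherits(trajectories, "chain_trajectory")) {
    chain <- attr(trajectories, "chain")
    if (is.null(burn_in)) burn_in <- default_burn_in(chain)
    X <- occupancy_matrix(trajectories)
    keep <- trajectories$t > burn_in
    if (sum(keep) < 2L) stop("not enough rows after burn-in.", call. = FALSE)
    X <- X[keep, , drop = FALSE]
  } else {
    stopifnot(is.list(trajectories), length(trajectories) >= 1L,
              !is.null(at))
    X <- t(vapply(trajectories, function(tr) {
      occupancy_matrix(tr)[match(at, tr$t), ]
    }, numeric(ncol(occupancy_matrix(trajectories[[1L]])))))
  }
  list(mu = unname(colMeans(X)),
       sigma = unname(stats::cov(X)),
       se_mu = unname(apply(X, 2L, stats::sd)) / sqrt(nrow(X)),
       n_obs = nrow(X))
}

#' Empirical two-time covariance
#'
#' Stationary lag-`s` cross-covariance matrices
#' `C(s)[i, j] = Cov(N_i^t, N_j^(t+s))` estimated from a single long
#' trajectory after burn-in; `C(0)` is the ordinary sample covariance.
#'
#' @param trajectory A `chain_trajectory`.
#' @param max_lag Largest lag `s`.
#' @param burn_in Rows with `t <= burn_in` are dropped; defaults to
#'   [default_burn_in()].
#' @return A list of `max_lag + 1` matrices named `"0" ... "max_lag"`.
#' @export
empirical_two_time_cov <- function(trajectory, max_lag, burn_in = NULL) {
  stopifnot(inherits(trajectory, "chain_trajectory"), max_lag >= 0)
  chain <- attr(trajectory, "chain")
  if (is.null(burn_in)) burn_in <- default_burn_in(chain)
  X <- occupancy_matrix(trajectory)[trajectory$t > burn_in, , drop = FALSE]
  n <- nrow(X)
  if (n <= max_lag + 1L) stop("trajectory too short for max_lag.",
                              call. = FALSE)
  lapply(stats::setNames(0:max_lag, 0:max_lag), function(s) {
    A <- X[seq_len(n - s), , drop = FALSE]
    B <- X[(1L + s):n, , drop = FALSE]
    m <- nrow(A)
    crossprod(sweep(A, 2L, colMeans(A)), sweep(B, 2L, colMeans(B))) / (m - 1)
  })
}

#' @export
print.chain_trajectory <- function(x, ...) {
  cat("<chain_trajectory> ", max(x$t), " steps, ",
      length(grep("^N[0-9]+$", names(x))), " states",
      if (!is.null(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")),
      "\n", sep = "")
  NextMethod()
}

#' Plot a trajectory
#'
#' Occupancy of each state against time.
#'
#' @param object A `chain_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chain_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", grep("^N[0-9]+$", names(object),
                                            value = TRUE))],
    -"t", names_to = "state", values_to = "occupancy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = "particles")
}
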