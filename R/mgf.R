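#' The H-map of an open chain
#'
#' The vector map `H_i(alpha) = log(e_i + sum_j Q[i, j] * exp(alpha_j))`
#' that transports the occupancy m.g.f. one step backward in time:
#' `G_{t+1}(alpha) = F(alpha) * G_t(H(alpha))`, with `F` the arrival m.g.f.
#' `H(0) = 0` exactly.
#'
#' @param chain An `open_chain`.
#' @param alpha Length-`S` finite numeric vector.
#' @return A length-`S` numeric vector.
#' @export
h_map <- function(chain, alpha) {
  stopifnot(inherits(chain, "open_chain"), length(alpha) == chain$S,
            all(is.finite(alpha)))
  arg <- chain$e + as.numeric(chain$Q %*% exp(alpha))
  stopifnot(all(arg > 0))
  log(arg)
}

#' Iterates of the H-map
#'
#' The r-fold composition `H^(r)`. The default `"power"` method uses the
#' closed form `H^(r)(alpha)_i = log(1 - sum_j (Q^r)[i, j] +
#' sum_j (Q^r)[i, j] * exp(alpha_j))`, which avoids accumulating log/exp
#' round-off; `"compose"` applies [h_map()] r times and is retained as an
#' independent check.
#'
#' @param chain An `open_chain`.
#' @param alpha Length-`S` finite numeric vector.
#' @param r Nonnegative integer; `r = 0` returns `alpha`.
#' @param method `"power"` (closed form) or `"compose"`.
#' @return A length-`S` numeric vector; tends to 0 geometrically in `r`.
#' @export
h_iterate <- function(chain, alpha, r, method = c("power", "compose")) {
  method <- match.arg(method)
  stopifnot(inherits(chain, "open_chain"), length(alpha) == chain$S,
            all(is.finite(alpha)), r >= 0, r == round(r))
  if (r == 0) return(as.numeric(alpha))
  if (method == "compose") {
    out <- as.numeric(alpha)
    for (k in seq_len(r)) out <- h_map(chain, out)
    return(out)
  }
  Qr <- matrix_power(chain$Q, r)
  arg <- 1 - rowSums(Qr) + as.numeric(Qr %*% exp(alpha))
  stopifnot(all(arg > 0))
  log(arg)
}

#' Integer power of a square matrix
#'
#' Exponentiation by squaring; `k = 0` gives the identity.
#'
#' @param A Square numeric matrix.
#' @param k Nonnegative integer.
#' @return A matrix of the same dimension.
#' @export
matrix_power <- function(A, k) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), k >= 0, k == round(k))
  out <- diag(nrow(A))
  base <- A
  k <- as.integer(k)
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2L
  }
  out
}

#' Finite-horizon occupancy m.g.f.
#'
#' `G_t(alpha) = G_0(H^(t)(alpha)) * prod_{r=0}^{t-1} F(H^(r)(alpha))` for a
#' stationary arrival protocol, where `G_0` is the m.g.f. of the initial
#' occupancy (default: the system starts empty, `G_0 = 1`).
#'
#' @param chain An `open_chain`.
#' @param protocol A stationary `arrival_protocol`.
#' @param alpha Length-`S` numeric vector.
#' @param t Nonnegative integer horizon; `t = 0` returns `mgf0(alpha)`.
#' @param mgf0 M.g.f. of the initial occupancy, a function of `alpha`.
#' @return A scalar; equals 1 at `alpha = 0`.
#' @export
occupancy_mgf <- function(chain, protocol, alpha, t,
                          mgf0 = function(alpha) 1) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S, t >= 0, t == round(t))
  alpha <- as.numeric(alpha)
  acc <- 1
  Qr <- diag(chain$S)
  ea <- exp(alpha)
  for (r in seq_len(t) - 1L) {
    hr <- log(1 - rowSums(Qr) + as.numeric(Qr %*% ea))
    acc <- acc * protocol$mgf(hr)
    Qr <- Qr %*% chain$Q
  }
  ht <- log(1 - rowSums(Qr) + as.numeric(Qr %*% ea))
  acc * mgf0(ht)
}

#' Stationary occupancy m.g.f.
#'
#' The infinite product `G_stat(alpha) = prod_{r>=0} F(H^(r)(alpha))`,
#' truncated at the first `r` with `max(abs(H^(r)(alpha))) < tol`. Converges
#' because the H-iterates decay geometrically at rate `rho < 1`.
#'
#' @param chain An `open_chain`.
#' @param protocol A stationary `arrival_protocol`.
#' @param alpha Length-`S` numeric vector.
#' @param tol Truncation tolerance on the sup-norm of the H-iterate.
#' @param r_max Iteration cap; exceeding it is an error.
#' @return A scalar with attribute `"r_used"`, the truncation index.
#' @export
stationary_mgf <- function(chain, protocol, alpha, tol = 1e-12,
                           r_max = 10000L) {
  stopifnot(inherits(chain, "open_chain"),
            inherits(protocol, "arrival_protocol"),
            protocol$S == chain$S, tol > 0, r_max >= 1)
  alpha <- as.numeric(alpha)
  acc <- 1
  Qr <- diag(chain$S)
  ea <- exp(alpha)
  r <- 0L
  repeat {
    hr <- log(1 - rowSums(Qr) + as.numeric(Qr %*% ea))
    if (max(abs(hr)) < tol) break
    acc <- acc * protocol$mgf(hr)
    Qr <- Qr %*% chain$Q
    r <- r + 1L
    if (r > r_max) {
      stop("stationary m.g.f. product did not converge within r_max = ",
           r_max, " factors (rho = ", signif(chain$rho, 4), ").",
           call. = FALSE)
    }
  }
  structure(acc, r_used = r)
}

#' Mean and covariance from an m.g.f.
#'
#' First two cumulants of a distribution from its moment generating function,
#' by central finite differences of the cumulant generating function
#' `log(mgf)` at 0 with one step of Richardson extrapolation. The Hessian is
#' symmetrized.
#'
#' @param mgf A function taking a length-`S` numeric vector and returning a
#'   positive scalar, finite near 0 with `mgf(0) = 1`.
#' @param S Dimension of the argument.
#' @param h Base differencing step on the log-m.g.f. scale. The Richardson
#'   step makes the truncation error `O(h^4)`, so a relatively coarse `h`
#'   is best: any noise in the m.g.f. evaluation (round-off, or the
#'   truncation of an infinite product) enters the Hessian divided by `h^2`.
#' @return A list with `mu` (length-`S` mean vector) and `sigma`
#'   (`S x S` covariance matrix).
#' @export
mgf_cumulants <- function(mgf, S, h = 1e-2) {
  stopifnot(is.function(mgf), S >= 1, h > 0)
  kgf <- function(alpha) log(as.numeric(mgf(alpha)))
  unit <- function(i) {
    v <- numeric(S)
    v[i] <- 1
    v
  }
  grad_at <- function(step) {
    vapply(seq_len(S), function(i) {
      (kgf(step * unit(i)) - kgf(-step * unit(i))) / (2 * step)
    }, numeric(1))
  }
  # Richardson: D = (4 D_{h/2} - D_h) / 3 kills the O(h^2) term
  mu <- (4 * grad_at(h / 2) - grad_at(h)) / 3

  hess_at <- function(step) {
    M <- matrix(0, S, S)
    f0 <- kgf(numeric(S))
    for (i in seq_len(S)) {
      ui <- unit(i)
      M[i, i] <- (kgf(step * ui) - 2 * f0 + kgf(-step * ui)) / step^2
      if (i < S) {
        for (j in (i + 1L):S) {
          uj <- unit(j)
          M[i, j] <- (kgf(step * (ui + uj)) + kgf(-step * (ui + uj)) -
                      kgf(step * (ui - uj)) - kgf(-step * (ui - uj))) /
                     (4 * step^2)
          M[j, i] <- M[i, j]
        }
      }
    }
    M
  }
  sigma <- (4 * hess_at(h / 2) - hess_at(h)) / 3
  list(mu = mu, sigma = (sigma + t(sigma)) / 2)
}
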