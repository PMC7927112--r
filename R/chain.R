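#' Construct an open Markov chain
#'
#' An open Markov chain is a system of non-interacting particles hopping on a
#' finite state space according to a sub-stochastic jump matrix `Q`. The
#' deficit of each row from 1 is the per-state escape probability: a particle
#' at state `i` jumps to state `j` with probability `Q[i, j]` and leaves the
#' system with probability `e[i] = 1 - sum(Q[i, ])`. Openness requires the
#' spectral radius of `Q` to be strictly below 1, so that the particle
#' population cannot grow without bound under a stationary inflow.
#'
#' @param Q Square numeric matrix with nonnegative entries and row sums at
#'   most 1 (within `1e-12`). May also be a single number for a one-state
#'   chain.
#' @param labels Optional character vector of state labels; defaults to
#'   `"1"`, `"2"`, ... or the dimnames of `Q`.
#' @param quiet If `TRUE`, suppress the reducibility/periodicity warning.
#'
#' @return An object of class `open_chain`: a list with elements `S` (number
#'   of states), `Q` (jump matrix), `e` (escape probability vector), `E`
#'   (diagonal escape matrix), `rho` (spectral radius of `Q`) and `labels`.
#'
#' @details The jump matrix need not be irreducible or aperiodic: all moment
#'   formulas implemented here require only `rho < 1`. A warning (not an
#'   error) is emitted for reducible or periodic structure, since some
#'   classical results about the occupancy distribution assume it.
#'
#' @examples
#' ch <- open_chain(matrix(c(0, .5, .25, .25, 0, .25, .5, .25, .25), 3, 3,
#'                         byrow = TRUE))
#' escape_vector(ch) # 1/4, 1/2, 0
#' @export
open_chain <- function(Q, labels = NULL, quiet = FALSE) {
  if (is.numeric(Q) && is.null(dim(Q))) {
    if (length(Q) != 1L) {
      stop("`Q` must be a square matrix (or a single number).", call. = FALSE)
    }
    Q <- matrix(Q, 1L, 1L)
  }
  if (!is.matrix(Q) || !is.numeric(Q)) {
    stop("`Q` must be a numeric matrix.", call. = FALSE)
  }
  if (nrow(Q) != ncol(Q)) {
    stop("`Q` must be square.", call. = FALSE)
  }
  if (any(!is.finite(Q))) {
    stop("`Q` must have finite entries.", call. = FALSE)
  }
  if (any(Q < 0)) {
    stop("`Q` must be nonnegative.", call. = FALSE)
  }
  S <- nrow(Q)
  row_sums <- rowSums(Q)
  if (any(row_sums > 1 + 1e-12)) {
    stop("every row of `Q` must sum to at most 1 (sub-stochastic).",
         call. = FALSE)
  }
  rho <- spectral_radius(Q)
  if (rho >= 1 - 1e-12) {
    stop("not an open chain: spectral radius of `Q` is ", signif(rho, 6),
         " but must be strictly below 1.", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(Q) %||% as.character(seq_len(S))
  }
  stopifnot(length(labels) == S)
  e <- pmin(pmax(1 - row_sums, 0), 1)
  dimnames(Q) <- NULL
  chain <- structure(
    list(S = S, Q = Q, e = e, E = diag(e, nrow = S), rho = rho,
         labels = as.character(labels)),
    class = "open_chain"
  )
  if (!quiet) {
    if (!chain_is_irreducible(Q)) {
      warning("`Q` is reducible; moment formulas remain valid (rho < 1).",
              call. = FALSE)
    } else if (!chain_is_aperiodic(Q)) {
      warning("`Q` is periodic; moment formulas remain valid (rho < 1).",
              call. = FALSE)
    }
  }
  chain
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral radius of a square matrix
#'
#' Largest modulus among the eigenvalues, computed with [base::eigen()].
#'
#' @param Q A square numeric matrix (or an `open_chain`, whose stored value
#'   is returned).
#' @return A single nonnegative number.
#' @export
spectral_radius <- function(Q) {
  if (inherits(Q, "open_chain")) return(Q$rho)
  if (is.numeric(Q) && is.null(dim(Q)) && length(Q) == 1L) return(abs(Q))
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (nrow(Q) == 1L) return(abs(Q[1, 1]))
  max(Mod(eigen(Q, only.values = TRUE)$values))
}

#' Escape probabilities of an open chain
#'
#' `escape_vector()` returns the per-state probabilities of leaving the
#' system in one step, `e_i = 1 - sum_j Q[i, j]`; `escape_matrix()` returns
#' the diagonal matrix `diag(e)` used in the outflow moment formulas.
#'
#' @param chain An `open_chain`.
#' @return A length-`S` numeric vector, or an `S x S` diagonal matrix.
#' @export
escape_vector <- function(chain) {
  stopifnot(inherits(chain, "open_chain"))
  chain$e
}

#' @rdname escape_vector
#' @export
escape_matrix <- function(chain) {
  stopifnot(inherits(chain, "open_chain"))
  chain$E
}

# Reachability test on the sparsity pattern: strongly connected iff
# (I + A)^(S-1) has no zero entry, with A the boolean adjacency of Q.
chain_is_irreducible <- function(Q) {
  S <- nrow(Q)
  if (S == 1L) return(TRUE)
  reach <- (Q > 0) | diag(TRUE, S)
  for (k in seq_len(ceiling(log2(S)))) {
    reach <- (reach %*% reach) > 0
  }
  all(reach)
}

# Period of a strongly connected directed graph: gcd over all edges (u, v)
# of level(u) + 1 - level(v), with levels from a BFS tree. Aperiodic iff 1.
# Chains with no internal edges at all (Q == 0) are treated as aperiodic.
chain_is_aperiodic <- function(Q) {
  S <- nrow(Q)
  A <- Q > 0
  if (!any(A)) return(TRUE)
  if (S == 1L) return(A[1, 1])
  level <- rep(NA_integer_, S)
  level[1L] <- 0L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      vs <- which(A[u, ] & is.na(level))
      level[vs] <- level[u] + 1L
      nxt <- c(nxt, vs)
    }
    frontier <- nxt
  }
  g <- 0L
  for (u in which(!is.na(level))) {
    for (v in which(A[u, ] & !is.na(level))) {
      g <- gcd2(g, abs(level[u] + 1L - level[v]))
      if (g == 1L) return(TRUE)
    }
  }
  g == 1L
}

gcd2 <- function(a, b) {
  while (b != 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

#' Fundamental matrix of an open chain
#'
#' `(I - Q)^{-1} = sum_k Q^k`, the expected number of visits to each state
#' before escape. Exists because `rho(Q) < 1`.
#'
#' @param chain An `open_chain`.
#' @return An `S x S` matrix with nonnegative entries.
#' @export
fundamental_matrix <- function(chain) {
  stopifnot(inherits(chain, "open_chain"))
  solve(diag(chain$S) - chain$Q)
}

#' @export
print.open_chain <- function(x, ...) {
  cat("<open_chain> ", x$S, " state(s), spectral radius ",
      signif(x$rho, 4), "\n", sep = "")
  cat("escape probabilities: ", paste(signif(x$e, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Chain summary as a tibble
#'
#' One row per state: label, row sum of `Q`, escape probability, and the
#' stationary expected visit count from that state (row sums of the
#' fundamental matrix).
#'
#' @param x An `open_chain`.
#' @param ... Unused.
#' @return A tibble with columns `state`, `row_sum`, `escape`,
#'   `expected_visits`.
#' @export
tidy.open_chain <- function(x, ...) {
  tibble::tibble(
    state = x$labels,
    row_sum = rowSums(x$Q),
    escape = x$e,
    expected_visits = rowSums(fundamental_matrix(x))
  )
}

#' @export
glance.open_chain <- function(x, ...) {
  tibble::tibble(
    n_states = x$S,
    spectral_radius = x$rho,
    min_escape = min(x$e),
    max_escape = max(x$e),
    irreducible = chain_is_irreducible(x$Q),
    aperiodic = chain_is_aperiodic(x$Q)
  )
}
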