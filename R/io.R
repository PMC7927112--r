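#' Read a jump matrix from disk
#'
#' Accepts either a JSON file (a nested array, or an object with a `Q`
#' field) or a headerless CSV of numbers.
#'
#' @param path File path; format inferred from the `.json` / `.csv`
#'   extension.
#' @param ... Passed to [open_chain()].
#' @return An `open_chain`.
#' @export
read_chain <- function(path, ...) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  Q <- switch(
    ext,
    json = {
      parsed <- jsonlite::fromJSON(path)
      if (is.list(parsed) && !is.null(parsed$Q)) parsed <- parsed$Q
      as.matrix(parsed)
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported chain file extension: .", ext, call. = FALSE)
  )
  dimnames(Q) <- NULL
  open_chain(Q, ...)
}

#' Write a chain summary as JSON
#'
#' `{S, row_sums, e, rho}` — enough to sanity-check a chain file without
#' loading it into R.
#'
#' @param chain An `open_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_summary <- function(chain, path) {
  stopifnot(inherits(chain, "open_chain"))
  jsonlite::write_json(
    list(S = chain$S, row_sums = rowSums(chain$Q), e = chain$e,
         rho = chain$rho),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Build an arrival protocol from a config entry
#'
#' Types: `constant` (`j0`), `bernoulli` (`p`), `poisson` (`lambda`),
#' `coupled_bernoulli` (`p`, scalar), `pmf` (`values` matrix + `prob`, or
#' `table` path to a CSV with columns `j1 ... jS, prob`).
#'
#' @param spec A named list, e.g. `list(type = "bernoulli", p = c(.1, 0))`.
#' @param base Directory against which a relative `table` path is resolved.
#' @return An `arrival_protocol`.
#' @export
protocol_from_config <- function(spec, base = ".") {
  if (is.null(spec$type)) {
    stop("protocol spec must have a `type` field.", call. = FALSE)
  }
  switch(
    spec$type,
    constant = arrival_constant(required(spec, "j0")),
    bernoulli = arrival_bernoulli(required(spec, "p")),
    poisson = arrival_poisson(required(spec, "lambda")),
    coupled_bernoulli = arrival_coupled_bernoulli(required(spec, "p")),
    pmf = {
      if (!is.null(spec$table)) {
        tab <- utils::read.csv(resolve_path(spec$table, base))
        arrival_pmf(as.matrix(tab[, -ncol(tab), drop = FALSE]),
                    tab[[ncol(tab)]])
      } else {
        arrival_pmf(do.call(rbind, lapply(spec$values, as.numeric)),
                    as.numeric(required(spec, "prob")))
      }
    },
    stop("unknown protocol type: ", spec$type, call. = FALSE)
  )
}

required <- function(spec, field) {
  if (is.null(spec[[field]])) {
    stop("protocol spec of type '", spec$type, "' needs field `", field,
         "`.", call. = FALSE)
  }
  spec[[field]]
}

resolve_path <- function(path, base) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base, path)
}

#' Load a run configuration
#'
#' JSON with fields: `Q` (inline nested array) or `chain` (path to a chain
#' file), `protocol` (see [protocol_from_config()]), and optional `n0`
#' (default zeros), `steps` (default 10000), `replicates` (default 1),
#' `burn_in` (default from [default_burn_in()]), `seed` (default 1),
#' `max_lag` (default 10). Validation errors name the offending field.
#'
#' @param path Path to the JSON config.
#' @return A list of class `run_config` with the chain and protocol
#'   constructed and all defaults filled.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  base <- dirname(normalizePath(path))
  chain <- if (!is.null(cfg$Q)) {
    Q <- as.matrix(cfg$Q)
    if (!is.numeric(Q)) stop("config field `Q`: not numeric.", call. = FALSE)
    dimnames(Q) <- NULL
    open_chain(Q, quiet = TRUE)
  } else if (!is.null(cfg$chain)) {
    read_chain(resolve_path(cfg$chain, base), quiet = TRUE)
  } else {
    stop("config needs `Q` (inline matrix) or `chain` (file path).",
         call. = FALSE)
  }
  if (is.null(cfg$protocol)) {
    stop("config needs a `protocol` object.", call. = FALSE)
  }
  protocol <- protocol_from_config(as.list(cfg$protocol), base)
  if (protocol$S != chain$S) {
    stop("config: protocol dimension (", protocol$S,
         ") does not match chain (", chain$S, ").", call. = FALSE)
  }
  n0 <- if (is.null(cfg$n0)) numeric(chain$S) else check_counts(cfg$n0, "n0")
  if (length(n0) != chain$S) {
    stop("config field `n0`: wrong length.", call. = FALSE)
  }
  structure(
    list(chain = chain, protocol = protocol, n0 = n0,
         steps = as.integer(cfg$steps %||% 10000L),
         replicates = as.integer(cfg$replicates %||% 1L),
         burn_in = as.integer(cfg$burn_in %||% default_burn_in(chain)),
         seed = as.integer(cfg$seed %||% 1L),
         max_lag = as.integer(cfg$max_lag %||% 10L),
         raw = cfg),
    class = "run_config"
  )
}

#' Emit a fixture as a run configuration
#'
#' Writes a JSON config (inline `Q` plus protocol spec) that [load_config()]
#' round-trips, so the bundled examples can be driven from the command line.
#'
#' @param fixture A `chain_fixture`.
#' @param path Output path.
#' @param ... Extra top-level config fields (e.g. `steps`, `seed`).
#' @return `path`, invisibly.
#' @export
write_fixture_config <- function(fixture, path, ...) {
  stopifnot(inherits(fixture, "chain_fixture"))
  proto <- fixture$protocol
  spec <- switch(
    proto$kind,
    constant = list(type = "constant", j0 = proto$params$j0),
    bernoulli_product = list(type = "bernoulli", p = proto$params$p),
    poisson_product = list(type = "poisson", lambda = proto$params$lambda),
    coupled_bernoulli = list(type = "coupled_bernoulli",
                             p = proto$params$p),
    list(type = "pmf",
         values = apply(proto$params$values, 1L, identity,
                        simplify = FALSE),
         prob = proto$params$prob)
  )
  jsonlite::write_json(
    c(list(Q = fixture$chain$Q, protocol = spec), list(...)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
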