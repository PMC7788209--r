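#' Named random-number substreams
#'
#' Each stochastic process in the simulation (census, acuity mix, specialing,
#' absence, demand noise, temporary-staff availability) draws from its own
#' substream so that, for example, switching the flexible-staffing policy
#' (which changes how many availability draws are consumed) leaves the
#' census/absence/noise histories of a replication untouched. Substreams are
#' plain saved `.Random.seed` states, seeded deterministically from a single
#' base seed, and are advanced independently via [with_stream()].
#'
#' @param seed integer base seed for the replication.
#' @return An environment of class `sim_streams` holding one saved RNG state
#'   per process name.
#' @export
make_rng_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  names <- c("census", "acuity", "specialing", "absence", "noise",
             "availability")
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  for (i in seq_along(names)) {
    env[[names[i]]] <- .stream_state(derive_seed(seed, i))
  }
  class(env) <- "sim_streams"
  env
}

#' Derive a substream seed from a base seed
#'
#' Mixes the base seed with a stream index via a fixed multiplicative hash,
#' keeping the result in the 32-bit signed range accepted by [set.seed()].
#'
#' @param seed base seed.
#' @param index positive integer substream index.
#' @return integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

# Capture the freshly-seeded .Random.seed without disturbing the caller's RNG.
.stream_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  st <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  st
}

#' Evaluate an expression under a named substream
#'
#' Swaps the stream's saved state into `.Random.seed`, evaluates `expr`,
#' saves the advanced state back into the stream, and restores the caller's
#' RNG state.
#'
#' @param streams a `sim_streams` environment.
#' @param name substream name.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "sim_streams"))
  st <- streams[[name]]
  if (is.null(st)) stop("unknown substream: ", name)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", st, globalenv())
  on.exit({
    streams[[name]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}
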