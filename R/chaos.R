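#' Guarded tent map iteration
#'
#' One step of the tent chaotic map on the unit interval,
#' \eqn{x_{n+1} = \delta x_n} for \eqn{x_n < 1/2} and
#' \eqn{\delta (1 - x_n)} otherwise.  At the fully chaotic control value
#' \eqn{\delta = 2} the map's invariant density is uniform on (0, 1), which
#' is what makes it useful for spreading an initial population over the
#' search space.
#'
#' In exact arithmetic the raw map sends 0, 1/2, 1 (and every dyadic
#' rational) into the absorbing fixed point 0, and floating-point orbits
#' always hit such points: both branches are exact in double precision,
#' so the mantissa drains within about 50 steps.  A degeneracy guard
#' therefore replaces any raw iterate outside
#' \eqn{(\epsilon, 1-\epsilon)} (with \eqn{\epsilon = 10^{-9}}) by the
#' deterministic golden-ratio re-seed `frac(raw + n * 0.6180339887)`
#' clamped back into the open interval, where `n` is the iterate's index
#' within its stream (`n = 1` for a standalone `tent_next()` call).
#' Indexing the re-seed by `n` makes the guard events a Weyl sequence,
#' so the guarded stream is aperiodic with uniform long-run density.
#'
#' @param x current state, in \[0, 1\].
#' @param control tent control parameter \eqn{\delta > 0} (default 2).
#' @return Next state, guaranteed inside the open interval (0, 1) when
#'   `control = 2`.
#' @examples
#' tent_next(0.3)   # lower branch: 0.6
#' tent_next(0.75)  # upper branch: 0.5
#' @export
tent_next <- function(x, control = 2) {
  if (any(x < 0) || any(x > 1)) stop("tent map state must lie in [0, 1]")
  if (control <= 0) stop("control parameter must be positive")
  raw <- ifelse(x < 0.5, control * x, control * (1 - x))
  tent_guard(raw)
}

# golden-ratio conjugate used for deterministic re-seeding of collapsed orbits
.tent_eps <- 1e-9
.tent_golden <- 0.6180339887

tent_guard <- function(raw, step = 1) {
  bad <- raw <= .tent_eps | raw >= 1 - .tent_eps
  if (any(bad)) {
    reseed <- (raw[bad] + step * .tent_golden) %% 1
    raw[bad] <- pmin(pmax(reseed, .tent_eps), 1 - .tent_eps)
  }
  raw
}

# One guarded step inside a counted stream.  Both tent branches are exact
# in binary floating point (2*x is a shift; 1-x is exact for x in [0.5, 1]
# by the Sterbenz lemma), so every double-precision orbit drains its
# mantissa and collapses through exactly 0.5 -> 1.0 within about 50
# steps.  Re-seeding with a FIXED offset would therefore make the stream
# periodic; indexing the re-seed by the global step count turns the guard
# events into a golden-ratio Weyl sequence, which is equidistributed and
# never repeats, so the guarded stream stays aperiodic with (near)
# uniform long-run density.
tent_step <- function(x, step, control) {
  raw <- if (x < 0.5) control * x else control * (1 - x)
  tent_guard(raw, step)
}

#' Tent map orbit of a given length
#'
#' Successive guarded tent iterates starting from (and not including)
#' `seed_value`.  Deterministic given `seed_value`.
#'
#' @param seed_value initial state in the open interval (0, 1).
#' @param length number of iterates to produce (>= 1).
#' @param control tent control parameter (default 2).
#' @return Numeric vector of `length` iterates, all in (0, 1).
#' @examples
#' tent_sequence(0.3, 3)  # 0.6, 0.8, 0.4
#' @export
tent_sequence <- function(seed_value, length, control = 2) {
  if (length < 1L) stop("length must be >= 1")
  if (seed_value <= 0 || seed_value >= 1)
    stop("seed_value must lie strictly inside (0, 1)")
  s <- tent_stream(seed_value, control)
  tent_stream_next(s, length)
}

#' Matrix of chaotic initial values
#'
#' Fills a `rows x cols` matrix row-major from one continuous guarded tent
#' stream, so individual 1 consumes the first `cols` iterates, individual 2
#' the next `cols`, and so on.
#'
#' @param rows,cols matrix dimensions (>= 1).
#' @param seed_value tent stream seed in (0, 1).
#' @param control tent control parameter (default 2).
#' @return Numeric matrix with all entries in (0, 1).
#' @export
chaotic_init_matrix <- function(rows, cols, seed_value, control = 2) {
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  matrix(tent_sequence(seed_value, rows * cols, control),
         nrow = rows, ncol = cols, byrow = TRUE)
}

#' Stateful tent stream
#'
#' A mutable chaotic stream used by the mutation operator: each call to
#' [tent_stream_next()] advances the stream and returns the next guarded
#' iterate(s).
#'
#' @param seed_value initial state in (0, 1).
#' @param control tent control parameter (default 2).
#' @return An object of class `tent_stream`.
#' @export
tent_stream <- function(seed_value, control = 2) {
  if (seed_value <= 0 || seed_value >= 1)
    stop("seed_value must lie strictly inside (0, 1)")
  env <- new.env(parent = emptyenv())
  env$state <- seed_value
  env$control <- control
  env$step <- 0L           # total iterates drawn, indexes the Weyl re-seed
  class(env) <- "tent_stream"
  env
}

#' @rdname tent_stream
#' @param stream a [tent_stream()] object.
#' @param n number of iterates to draw (default 1).
#' @export
tent_stream_next <- function(stream, n = 1L) {
  out <- numeric(n)
  x <- stream$state
  step <- stream$step
  for (i in seq_len(n)) {
    step <- step + 1
    x <- tent_step(x, step, stream$control)
    out[i] <- x
  }
  stream$state <- x
  stream$step <- step
  out
}

# Map an integer PRNG seed to a tent seed in (0, 1); used when callers give
# only one integer seed for the whole pipeline.
chaos_seed_from_int <- function(seed) {
  s <- (as.numeric(seed) * .tent_golden) %% 1
  pmin(pmax(s, 0.1), 0.9)
}
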