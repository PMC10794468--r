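#' Configure a single-embryo elementary cellular automaton
#'
#' Each simulated embryo develops as a one-dimensional elementary cellular
#' automaton (ECA) of `length` binary cells that must solve the majority
#' (density classification) problem: starting from a random configuration with
#' a 60/40 majority of 1-cells, development is successful when every cell has
#' converged to 1 within the timestep budget. The budget defaults to half the
#' cell count, the usual horizon quoted for efficient density classification
#' under the GKL rule.
#'
#' @param length Number of cells in the automaton (default 149).
#' @param steps Timestep budget; defaults to `floor(length / 2)`.
#' @param init_ones Number of 1-cells placed at time zero; defaults to
#'   `round(0.6 * length)` so that 1 is the true majority. Under
#'   `init_mode = "bernoulli"` this is the expected count instead.
#' @param init_mode `"exact"` places exactly `init_ones` ones at uniformly
#'   random positions; `"bernoulli"` draws each cell independently with
#'   probability `init_ones / length`.
#' @param boundary `"periodic"` (ring, the default) or `"fixed"`, in which
#'   neighbour indices are clamped at the array ends.
#'
#' @return An object of class `eca_config`.
#' @examples
#' cfg <- eca_config()
#' cfg$steps # 74
#' @export
eca_config <- function(length = 149L,
                       steps = NULL,
                       init_ones = NULL,
                       init_mode = c("exact", "bernoulli"),
                       boundary = c("periodic", "fixed")) {
  init_mode <- match.arg(init_mode)
  boundary <- match.arg(boundary)
  length <- as.integer(length)
  if (is.na(length) || length < 7L) {
    abort("`length` must be an integer >= 7 (the GKL rule reaches 3 cells away).")
  }
  if (is.null(steps)) steps <- length %/% 2L
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) abort("`steps` must be a positive integer.")
  if (is.null(init_ones)) init_ones <- as.integer(round(0.6 * length))
  init_ones <- as.integer(init_ones)
  if (is.na(init_ones) || init_ones <= 0L || init_ones >= length) {
    abort("`init_ones` must satisfy 0 < init_ones < length.")
  }
  structure(
    list(length = length, steps = steps, init_ones = init_ones,
         init_mode = init_mode, boundary = boundary),
    class = "eca_config"
  )
}

#' @export
print.eca_config <- function(x, ...) {
  cat(sprintf(
    "<eca_config> %d cells, %d steps, %d initial ones (%s init, %s boundary)\n",
    x$length, x$steps, x$init_ones, x$init_mode, x$boundary
  ))
  invisible(x)
}

#' Draw a random initial ECA state
#'
#' @param config An [eca_config()].
#' @return Integer vector of 0/1 of length `config$length`. With the default
#'   exact-count initialization the vector sums to `config$init_ones`.
#' @examples
#' set.seed(1)
#' sum(eca_init(eca_config())) # 89
#' @export
eca_init <- function(config = eca_config()) {
  stopifnot(inherits(config, "eca_config"))
  L <- config$length
  if (config$init_mode == "exact") {
    v <- integer(L)
    v[sample.int(L, config$init_ones)] <- 1L
  } else {
    v <- as.integer(runif(L) < config$init_ones / L)
  }
  v
}

# Column index helper for the matrix engines: offset k on a ring of L cells,
# or clamped at the ends for a fixed boundary.
.shift_idx <- function(L, k, boundary) {
  idx <- seq_len(L) + k
  if (boundary == "periodic") ((idx - 1L) %% L) + 1L else pmin(pmax(idx, 1L), L)
}

#' One synchronous GKL update of a batch of ECA states
#'
#' The Gacs--Kurdyumov--Levin rule: a 0-cell takes the majority of itself and
#' its neighbours at offsets -1 and -3; a 1-cell the majority of itself and
#' offsets +1 and +3. It is the classic near-solver of the density
#' classification task and stands in for a correctly functioning developmental
#' program.
#'
#' @param states Integer matrix with one ECA state per row (a plain 0/1 vector
#'   is accepted and returned as a vector).
#' @param boundary `"periodic"` or `"fixed"`.
#' @return Updated states, same shape and type as the input.
#' @examples
#' gkl_update(c(1, 1, 1, 1, 1, 1, 1)) # homogeneous fixed point
#' @export
gkl_update <- function(states, boundary = "periodic") {
  vec <- is.null(dim(states))
  S <- if (vec) matrix(as.integer(states), nrow = 1L) else states
  L <- ncol(S)
  Sm1 <- S[, .shift_idx(L, -1L, boundary), drop = FALSE]
  Sm3 <- S[, .shift_idx(L, -3L, boundary), drop = FALSE]
  Sp1 <- S[, .shift_idx(L, +1L, boundary), drop = FALSE]
  Sp3 <- S[, .shift_idx(L, +3L, boundary), drop = FALSE]
  maj0 <- (S + Sm1 + Sm3) >= 2L
  maj1 <- (S + Sp1 + Sp3) >= 2L
  out <- ifelse(S == 1L, maj1, maj0)
  storage.mode(out) <- "integer"
  if (vec) out[1L, ] else out
}

#' One synchronous random-imitation (noise) update
#'
#' The impaired alternative to [gkl_update()]: every cell copies the current
#' value of one uniformly chosen immediate neighbour (offset -1 or +1). This
#' voter-style rule models teratogen-disrupted information processing; it
#' preserves homogeneous states but cannot reliably solve the majority task.
#'
#' @inheritParams gkl_update
#' @return Updated states, same shape and type as the input.
#' @export
random_update <- function(states, boundary = "periodic") {
  vec <- is.null(dim(states))
  S <- if (vec) matrix(as.integer(states), nrow = 1L) else states
  n <- nrow(S)
  L <- ncol(S)
  off <- matrix(sample(c(-1L, 1L), n * L, replace = TRUE), n, L)
  col <- matrix(rep(seq_len(L), each = n), n, L)
  idx <- col + off
  idx <- if (boundary == "periodic") ((idx - 1L) %% L) + 1L else pmin(pmax(idx, 1L), L)
  out <- matrix(S[cbind(rep(seq_len(n), times = L), as.vector(idx))], n, L)
  storage.mode(out) <- "integer"
  if (vec) out[1L, ] else out
}

#' Has an ECA state solved the majority problem?
#'
#' Development is counted as successful when all cells equal 1 (the initial
#' majority value).
#'
#' @param state Integer 0/1 vector, or a matrix with one state per row.
#' @return Logical scalar (or vector, one per row).
#' @export
eca_success <- function(state) {
  if (is.null(dim(state))) all(state == 1L) else rowSums(state) == ncol(state)
}

#' Run one embryo ECA without noise
#'
#' Iterates [gkl_update()] from a random initial state for up to
#' `config$steps` steps and reports whether the all-ones state was reached at
#' any point (homogeneous states are fixed points, so this equals success at
#' the final step).
#'
#' @param config An [eca_config()].
#' @return `TRUE` if the automaton converged to all ones within the budget.
#' @examples
#' set.seed(1)
#' run_noise_free(eca_config())
#' @export
run_noise_free <- function(config = eca_config()) {
  stopifnot(inherits(config, "eca_config"))
  s <- eca_init(config)
  if (eca_success(s)) return(TRUE)
  for (t in seq_len(config$steps)) {
    s <- gkl_update(s, config$boundary)
    if (eca_success(s)) return(TRUE)
  }
  FALSE
}
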