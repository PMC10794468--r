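clamp01 <- function(x) pmin(1, pmax(0, x))

#' Apply one timestep of teratogen-like noise to a health value
#'
#' With probability `p_noise` the health value is decremented by `n_dec`
#' (subtracted by default, or scaled by `1 - n_dec` under the multiplicative
#' mode); otherwise it is returned unchanged. Vectorised over `health`;
#' exposure is drawn independently per element from the current RNG stream.
#'
#' @param health Numeric vector of health values in `[0, 1]`.
#' @param p_noise Exposure probability per element.
#' @param n_dec Decrement parameter in `[0, 1]`.
#' @param decrement `"subtractive"` or `"multiplicative"`.
#' @return Numeric vector of updated health values, clamped to `[0, 1]`.
#' @examples
#' apply_noise(1, p_noise = 1, n_dec = 0.7) # 0.3 with certainty
#' @export
apply_noise <- function(health, p_noise, n_dec,
                        decrement = c("subtractive", "multiplicative")) {
  decrement <- match.arg(decrement)
  hit <- runif(length(health)) < p_noise
  health[hit] <- decrement_health(health[hit], n_dec, decrement)
  health
}

decrement_health <- function(health, n_dec, decrement) {
  if (decrement == "multiplicative") clamp01(health * (1 - n_dec))
  else clamp01(health - n_dec)
}

#' Mix a noise-affected embryo's health with its neighbours'
#'
#' Returns the weighted average
#' \deqn{(w_s h + w_b \sum_{j \in nb} h_j + w_n \sum_{k \in nn} h_k) /
#'       (w_s + w_b |nb| + w_n |nn|)}
#' over the participating neighbours supplied, clamped to `[0, 1]`. With no
#' neighbours the embryo's own health is returned unchanged.
#'
#' @param health The embryo's own (post-noise) health value.
#' @param nb_health Numeric vector of participating immediate-neighbour
#'   healths (possibly empty).
#' @param nn_health Numeric vector of participating neighbour's-neighbour
#'   healths (possibly empty).
#' @param w_self,w_nb,w_nn Signaling weights.
#' @return Mixed health value.
#' @examples
#' mix_health(0.3, rep(1, 8), rep(1, 16)) # (0.3 + 8 + 4) / 13
#' @export
mix_health <- function(health, nb_health = numeric(), nn_health = numeric(),
                       w_self = 1, w_nb = 1, w_nn = 0.25) {
  num <- w_self * health + w_nb * sum(nb_health) + w_nn * sum(nn_health)
  den <- w_self + w_nb * length(nb_health) + w_nn * length(nn_health)
  clamp01(num / den)
}

#' Integrate supportive signals into an embryo's health
#'
#' The supportive signal is the normalized weighted average of the broadcast
#' values received from participating senders (the embryo's own broadcast
#' included when present), scaled by the receiver's health deficit `1 - h`
#' under the default deficit-scaled mode, and applied as
#' `h <- h + h * S`, clamped to `[0, 1]`. With no participating senders the
#' health value is returned unchanged.
#'
#' @param health The embryo's current health value.
#' @param self_signal The embryo's own broadcast value, or `NULL` if it has
#'   not broadcast.
#' @param nb_signal,nn_signal Numeric vectors of broadcast values received
#'   from participating immediate neighbours / neighbour's neighbours.
#' @param w_self,w_nb,w_nn Signaling weights.
#' @param scaling `"deficit_scaled"` or `"unscaled"`.
#' @return Updated health value.
#' @examples
#' # isolated exposed embryo supported only by its own broadcast:
#' support_update(0.3, self_signal = 0.3) # 0.3 * (1 + 0.7 * 0.3) = 0.363
#' @export
support_update <- function(health, self_signal = NULL,
                           nb_signal = numeric(), nn_signal = numeric(),
                           w_self = 1, w_nb = 1, w_nn = 0.25,
                           scaling = c("deficit_scaled", "unscaled")) {
  scaling <- match.arg(scaling)
  has_self <- !is.null(self_signal)
  num <- w_nb * sum(nb_signal) + w_nn * sum(nn_signal) +
    if (has_self) w_self * self_signal else 0
  den <- w_nb * length(nb_signal) + w_nn * length(nn_signal) +
    if (has_self) w_self else 0
  if (den <= 0) return(health)
  s <- num / den
  if (scaling == "deficit_scaled") s <- (1 - health) * s
  clamp01(health + health * s)
}

#' Select the update rule from an embryo's health
#'
#' @param health Numeric vector of health values.
#' @param theta Threshold; GKL is used strictly above it, random imitation at
#'   or below it (health exactly at the threshold counts as impaired).
#' @return Character vector, `"gkl"` or `"random"`.
#' @examples
#' select_rule(c(0.5, 0.51), theta = 0.5) # "random" "gkl"
#' @export
select_rule <- function(health, theta = 0.5) {
  ifelse(health > theta, "gkl", "random")
}

place_locked <- function(n, fraction, layout, side) {
  k <- round(fraction * n)
  if (k == 0) return(logical(n))
  locked <- logical(n)
  if (layout == "random") {
    locked[sample.int(n, k)] <- TRUE
  } else if (layout == "checkerboard") {
    row <- (seq_len(n) - 1L) %/% side
    col <- (seq_len(n) - 1L) %% side
    idx <- which((row + col) %% 2L == 0L)
    locked[head(idx, k)] <- TRUE
    if (sum(locked) < k) locked[head(which(!locked), k - sum(locked))] <- TRUE
  } else { # half_plane
    locked[seq_len(k)] <- TRUE
  }
  locked
}

#' Simulate one cohort of developing embryos
#'
#' Runs the full collective simulation: `config$n` embryos on a square grid,
#' each an ECA, with per-timestep noise exposure, health mixing over received
#' broadcasts, supportive signaling (one timestep delayed), health-gated rule
#' selection and an optional locked (untreated, non-participating) fraction.
#' Each timestep applies, in order: (1) noise to every unlocked embryo;
#' (2) health mixing for embryos hit this step; (3) supportive-signal
#' integration (for all ever-exposed embryos under the default continuous
#' scope); (4) one ECA step per embryo under the rule selected by its current
#' health. Broadcasts for the next timestep are recorded from every
#' ever-exposed, unlocked embryo.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; when supplied the run is exactly
#'   reproducible.
#' @param keep_trajectories Keep the full per-embryo health trajectory matrix
#'   (steps x embryos) in the result.
#' @return An object of class `cohort_sim`: a list with `survival` (fraction
#'   of embryos whose ECA reached all-ones), `survival_exposed` (the same
#'   fraction among unlocked embryos), `embryos` (per-embryo tibble),
#'   `mean_health` (per-timestep mean health of unlocked embryos), `config`
#'   and `seed`.
#' @examples
#' res <- simulate_cohort(sim_config(n = 9, p_noise = 0), seed = 1)
#' res$survival
#' @export
simulate_cohort <- function(config, seed = NULL, keep_trajectories = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  eca <- config$eca
  L <- eca$length
  n_steps <- eca$steps
  grid <- cohort_grid(n, config$topology)
  w_self <- config$w_self
  w_nb <- if (config$signaling) config$w_nb else 0
  w_nn <- if (config$signaling && config$nn_enabled) config$w_nn else 0
  deficit_scaled <- config$support_scaling == "deficit_scaled"

  states <- matrix(0L, n, L)
  for (i in seq_len(n)) states[i, ] <- eca_init(eca)
  health <- rep(1, n)
  ever <- logical(n)
  locked <- place_locked(n, config$locked_fraction, config$locked_layout, grid$side)
  bcast <- rep(0, n)
  bcast_on <- logical(n)
  success <- eca_success(states)
  mean_health <- numeric(n_steps)
  traj <- if (keep_trajectories) matrix(NA_real_, n_steps, n) else NULL
  at_risk <- rep(TRUE, n) # one_shot exposure: each embryo is at risk once

  nb_sum <- function(x) as.vector(grid$W_nb %*% x)
  nn_sum <- function(x) as.vector(grid$W_nn %*% x)

  for (t in seq_len(n_steps)) {
    h_prev <- health

    # (1) noise exposure
    hit <- !locked & at_risk & runif(n) < config$p_noise
    if (config$exposure == "one_shot") at_risk <- rep(FALSE, n)
    health[hit] <- decrement_health(health[hit], config$n_dec, config$decrement)
    ever <- ever | hit
    h_stress <- health

    participating <- ever & !locked

    # (2) health mixing for embryos hit this step
    if (any(hit)) {
      snapshot <- if (config$mix_snapshot == "broadcast") h_prev else health
      if (config$mix_participants == "exposed") {
        num <- w_self * health + w_nb * nb_sum(snapshot * participating) +
          w_nn * nn_sum(snapshot * participating)
        den <- w_self + w_nb * nb_sum(participating) + w_nn * nn_sum(participating)
      } else {
        occupied <- rep(1, n)
        num <- w_self * health + w_nb * nb_sum(snapshot) + w_nn * nn_sum(snapshot)
        den <- w_self + w_nb * nb_sum(occupied) + w_nn * nn_sum(occupied)
      }
      health[hit] <- clamp01(num / den)[hit]
    }

    # (3) supportive signaling, sampled from the previous timestep
    supported <- if (config$support_scope == "continuous") participating else hit
    if (any(supported) && any(bcast_on)) {
      num <- w_self * bcast * bcast_on + w_nb * nb_sum(bcast * bcast_on) +
        w_nn * nn_sum(bcast * bcast_on)
      den <- w_self * bcast_on + w_nb * nb_sum(bcast_on) + w_nn * nn_sum(bcast_on)
      s <- ifelse(den > 0, num / den, 0)
      if (deficit_scaled) s <- (1 - health) * s
      health[supported] <- clamp01(health + health * s)[supported]
    }

    # record broadcasts for t + 1
    bcast <- if (config$broadcast_content == "stress") h_stress else health
    bcast_on <- ever & !locked

    # (4) ECA development under the health-gated rule
    gkl <- locked | health > config$theta
    if (any(gkl)) {
      states[gkl, ] <- gkl_update(states[gkl, , drop = FALSE], eca$boundary)
    }
    if (any(!gkl)) {
      states[!gkl, ] <- random_update(states[!gkl, , drop = FALSE], eca$boundary)
    }
    success <- success | eca_success(states)

    mean_health[t] <- if (any(!locked)) mean(health[!locked]) else 1
    if (keep_trajectories) traj[t, ] <- health
  }

  embryos <- grid$layout
  embryos$health <- health
  embryos$ever_exposed <- ever
  embryos$locked <- locked
  embryos$success <- success

  structure(
    list(
      survival = mean(success),
      survival_exposed = if (any(!locked)) mean(success[!locked]) else NA_real_,
      embryos = embryos,
      mean_health = mean_health,
      health_trajectories = traj,
      config = config,
      seed = seed
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> n=%d: survival %.3f (%d/%d embryos all-ones)\n",
    x$config$n, x$survival, sum(x$embryos$success), x$config$n
  ))
  invisible(x)
}

#' @describeIn simulate_cohort Per-embryo results as a tibble (grid position,
#'   final health, exposure and lock status, success flag).
#' @param x A `cohort_sim` object.
#' @param ... Unused.
#' @exportS3Method
tidy.cohort_sim <- function(x, ...) {
  as_tibble(x$embryos)
}

#' @describeIn simulate_cohort One-row summary tibble.
#' @exportS3Method
glance.cohort_sim <- function(x, ...) {
  tibble(
    n = x$config$n,
    survival = x$survival,
    survival_exposed = x$survival_exposed,
    n_success = sum(x$embryos$success),
    n_locked = sum(x$embryos$locked),
    mean_final_health = mean(x$embryos$health),
    steps = x$config$eca$steps
  )
}
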