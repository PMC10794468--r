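#' Configure a cohort (CEMA) simulation
#'
#' Collects every model parameter and every documented interpretation switch
#' for the collective-development simulation. The defaults are the study
#' conditions: per-embryo per-timestep exposure probability 0.8, health
#' decrement 0.7, rule-selection threshold 0.5, signaling weights 1 (self),
#' 1 (immediate neighbours) and 0.25 (neighbour's neighbours), 149-cell ECAs
#' run for 74 steps.
#'
#' @param n Cohort size (number of embryos).
#' @param p_noise Per-embryo per-timestep probability of being affected by
#'   noise (teratogen exposure), in `[0, 1]`.
#' @param n_dec Health decrement applied on exposure, in `[0, 1]`. Under the
#'   default `decrement = "subtractive"` the health value drops by `n_dec`
#'   (floored at 0); `"multiplicative"` scales it by `1 - n_dec`.
#' @param theta Health threshold for rule selection: an embryo's cells follow
#'   the GKL rule when health exceeds `theta`, and the random-imitation rule
#'   when health is at or below it.
#' @param w_self,w_nb,w_nn Base signaling weights of the embryo itself, its
#'   immediate neighbours and its neighbour's neighbours.
#' @param signaling Master switch: `FALSE` zeroes `w_nb` and `w_nn` in both
#'   health mixing and supportive signaling (the no-communication control).
#' @param nn_enabled `FALSE` zeroes only `w_nn` (the neighbour's-neighbours
#'   ablation).
#' @param locked_fraction Fraction of embryos locked at health 1. Locked
#'   embryos model untreated cohort members: never exposed, never broadcast,
#'   never receive, but still develop under GKL.
#' @param replicates Default replicate count used by the sweep harness.
#' @param eca An [eca_config()] describing the per-embryo automaton.
#' @param decrement `"subtractive"` (default) or `"multiplicative"`; see
#'   `n_dec`.
#' @param exposure `"per_step"` (default; exposure is drawn independently per
#'   embryo per timestep) or `"one_shot"` (each embryo is at risk once, at the
#'   first timestep).
#' @param topology Grid neighbourhood passed to [cohort_grid()].
#' @param mix_snapshot Health values that noise-affected embryos average over
#'   during mixing: `"broadcast"` (default) uses the healths broadcast at the
#'   end of the previous timestep, so all incoming information is one step
#'   old; `"current"` uses the neighbours' already noise-degraded healths of
#'   the current timestep.
#' @param broadcast_content What an exposed embryo's broadcast carries:
#'   `"stress"` (default) the health value immediately after the noise phase
#'   (the distress level actually signalled), `"end_of_step"` the value after
#'   all health updates.
#' @param support_scope `"continuous"` (default): once exposed, an embryo
#'   integrates supportive signals at every subsequent timestep until the end
#'   of the simulation; `"affected_only"`: only at timesteps in which it was
#'   itself hit by noise.
#' @param support_scaling `"deficit_scaled"` (default) multiplies the
#'   normalized support signal by the receiver's health deficit `1 - h`, so
#'   healthy embryos largely ignore support; `"unscaled"` omits that factor.
#' @param mix_participants `"exposed"` (default) averages only over
#'   participating (ever-exposed, unlocked) embryos; `"all"` includes every
#'   occupied neighbour cell in the average.
#' @param locked_layout How locked embryos are placed: `"random"` (default),
#'   `"checkerboard"`, or `"half_plane"`.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n = 9)
#' cfg$p_noise
#' @export
sim_config <- function(n = 1L,
                       p_noise = 0.8,
                       n_dec = 0.7,
                       theta = 0.5,
                       w_self = 1,
                       w_nb = 1,
                       w_nn = 0.25,
                       signaling = TRUE,
                       nn_enabled = TRUE,
                       locked_fraction = 0,
                       replicates = 50L,
                       eca = eca_config(),
                       decrement = c("subtractive", "multiplicative"),
                       exposure = c("per_step", "one_shot"),
                       topology = c("moore", "von_neumann"),
                       mix_snapshot = c("broadcast", "current"),
                       broadcast_content = c("stress", "end_of_step"),
                       support_scope = c("continuous", "affected_only"),
                       support_scaling = c("deficit_scaled", "unscaled"),
                       mix_participants = c("exposed", "all"),
                       locked_layout = c("random", "checkerboard", "half_plane")) {
  cfg <- list(
    n = as.integer(n), p_noise = p_noise, n_dec = n_dec, theta = theta,
    w_self = w_self, w_nb = w_nb, w_nn = w_nn,
    signaling = isTRUE(signaling), nn_enabled = isTRUE(nn_enabled),
    locked_fraction = locked_fraction, replicates = as.integer(replicates),
    eca = eca,
    decrement = match.arg(decrement),
    exposure = match.arg(exposure),
    topology = match.arg(topology),
    mix_snapshot = match.arg(mix_snapshot),
    broadcast_content = match.arg(broadcast_content),
    support_scope = match.arg(support_scope),
    support_scaling = match.arg(support_scaling),
    mix_participants = match.arg(mix_participants),
    locked_layout = match.arg(locked_layout)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk01 <- function(value, key) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < 0 || value > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1] (got %s).",
                    key, deparse(value)))
    }
  }
  if (is.na(cfg$n) || cfg$n < 1L) abort("`n` must be a positive integer.")
  chk01(cfg$p_noise, "p_noise")
  chk01(cfg$n_dec, "n_dec")
  chk01(cfg$theta, "theta")
  chk01(cfg$locked_fraction, "locked_fraction")
  for (key in c("w_self", "w_nb", "w_nn")) {
    w <- cfg[[key]]
    if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", key))
    }
  }
  if (is.na(cfg$replicates) || cfg$replicates < 1L) {
    abort("`replicates` must be a positive integer.")
  }
  if (!inherits(cfg$eca, "eca_config")) abort("`eca` must be an `eca_config`.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> n=%d  p_noise=%g  n_dec=%g (%s)  theta=%g\n",
           "  weights self/nb/nn = %g/%g/%g  signaling=%s  nn=%s  locked=%g\n",
           "  eca: %d cells x %d steps | %s grid, %s mixing, %s support\n"),
    x$n, x$p_noise, x$n_dec, x$decrement, x$theta,
    x$w_self, x$w_nb, x$w_nn, x$signaling, x$nn_enabled, x$locked_fraction,
    x$eca$length, x$eca$steps, x$topology, x$mix_snapshot, x$support_scope
  ))
  invisible(x)
}
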