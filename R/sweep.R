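# Deterministic per-replicate seed, comparable across conditions at fixed
# (n, replicate). Kept below 2^31 - 1.
replicate_seed <- function(master, condition, n, replicate) {
  cond_id <- sum(utf8ToInt(condition))
  as.integer((as.numeric(master) * 48271 + cond_id * 1000003 +
                as.numeric(n) * 7919 + as.numeric(replicate) * 104729) %%
               2147483587) + 1L
}

condition_config <- function(condition, base) {
  switch(condition,
    cema = base,
    no_signaling = modify_config(base, signaling = FALSE),
    half_untreated = modify_config(base, locked_fraction = 0.5),
    no_nn = modify_config(base, nn_enabled = FALSE),
    abort(sprintf("Unknown condition '%s'.", condition))
  )
}

modify_config <- function(config, ...) {
  cfg <- unclass(config)
  changes <- list(...)
  cfg[names(changes)] <- changes
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

aggregate_sweep <- function(replicates, ci_level) {
  z <- qnorm(1 - (1 - ci_level) / 2)
  replicates |>
    group_by(.data$condition, .data$n) |>
    summarise(
      mean = mean(.data$survival),
      se = sd(.data$survival) / sqrt(n()),
      replicates = n(),
      .groups = "drop"
    ) |>
    mutate(
      ci_low = pmax(0, .data$mean - z * .data$se),
      ci_high = pmin(1, .data$mean + z * .data$se)
    ) |>
    select("condition", "n", "mean", "ci_low", "ci_high", "replicates")
}

#' Survival versus cohort size under each signaling condition
#'
#' Runs `replicates` independently seeded cohort simulations for every
#' combination of condition and cohort size and aggregates mean survival with
#' a normal-approximation confidence interval. Conditions: `"cema"` (full
#' model), `"no_signaling"` (neighbour weights zeroed), `"half_untreated"`
#' (half the cohort locked at health 1 and excluded from signaling) and
#' `"no_nn"` (neighbour's-neighbours weight zeroed).
#'
#' @param cohort_sizes Integer vector of cohort sizes. The default covers
#'   squares from a singleton to the 18 x 18 grid.
#' @param conditions Character vector of condition names (see above).
#' @param replicates Replicates per (condition, size) cell; defaults to the
#'   base configuration's `replicates`.
#' @param ci_level Confidence level for the aggregate interval.
#' @param config Base [sim_config()]; its `n` is overridden by
#'   `cohort_sizes`.
#' @param seed Master seed. Per-replicate seeds are derived deterministically
#'   from it together with the condition, size and replicate index, so
#'   conditions are comparable and reruns are bit-identical.
#' @return An object of class `cema_sweep` with tibbles `replicates`
#'   (condition, n, replicate, seed, survival, survival_exposed) and `summary`
#'   (condition, n, mean, ci_low, ci_high, replicates).
#' @examples
#' sw <- run_sweep(cohort_sizes = c(1, 4), replicates = 2, seed = 1)
#' sw$summary
#' @export
run_sweep <- function(cohort_sizes = c(1, 4, 9, 16, 25, 49, 100, 169, 256, 324),
                      conditions = c("cema", "no_signaling",
                                     "half_untreated", "no_nn"),
                      replicates = NULL,
                      ci_level = 0.95,
                      config = sim_config(),
                      seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(replicates)) replicates <- config$replicates
  if (replicates < 2L) abort("`replicates` must be at least 2.")
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  cells <- tidyr::expand_grid(
    condition = conditions, n = as.integer(cohort_sizes),
    replicate = seq_len(replicates)
  )
  rows <- purrr::pmap_dfr(cells, function(condition, n, replicate) {
    cfg <- condition_config(condition, modify_config(config, n = n))
    rep_seed <- replicate_seed(seed, condition, n, replicate)
    sim <- simulate_cohort(cfg, seed = rep_seed)
    tibble(
      condition = condition, n = n, replicate = replicate, seed = rep_seed,
      survival = sim$survival, survival_exposed = sim$survival_exposed
    )
  })
  structure(
    list(replicates = rows,
         summary = aggregate_sweep(rows, ci_level),
         ci_level = ci_level, config = config, seed = seed),
    class = "cema_sweep"
  )
}

#' Survival versus noise probability at fixed cohort size
#'
#' @param p_values Noise probabilities to test (default 0 to 1 in steps of
#'   0.1).
#' @param n Cohort size.
#' @inheritParams run_sweep
#' @return A `cema_sweep` whose tibbles carry `p_noise` instead of `n`.
#' @export
run_noise_sweep <- function(p_values = seq(0, 1, by = 0.1),
                            n = 100L,
                            replicates = NULL,
                            ci_level = 0.95,
                            config = sim_config(),
                            seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(replicates)) replicates <- config$replicates
  if (replicates < 2L) abort("`replicates` must be at least 2.")
  cells <- tidyr::expand_grid(p_noise = p_values, replicate = seq_len(replicates))
  rows <- purrr::pmap_dfr(cells, function(p_noise, replicate) {
    cfg <- modify_config(config, n = as.integer(n), p_noise = p_noise)
    rep_seed <- replicate_seed(seed, sprintf("noise%.3f", p_noise), n, replicate)
    sim <- simulate_cohort(cfg, seed = rep_seed)
    tibble(
      condition = "cema", p_noise = p_noise, n = as.integer(n),
      replicate = replicate, seed = rep_seed,
      survival = sim$survival, survival_exposed = sim$survival_exposed
    )
  })
  z <- qnorm(1 - (1 - ci_level) / 2)
  summary <- rows |>
    group_by(.data$p_noise) |>
    summarise(
      mean = mean(.data$survival),
      se = sd(.data$survival) / sqrt(n()),
      replicates = n(), .groups = "drop"
    ) |>
    mutate(ci_low = pmax(0, .data$mean - z * .data$se),
           ci_high = pmin(1, .data$mean + z * .data$se)) |>
    select("p_noise", "mean", "ci_low", "ci_high", "replicates")
  structure(
    list(replicates = rows, summary = summary,
         ci_level = ci_level, config = config, seed = seed),
    class = c("cema_noise_sweep", "cema_sweep")
  )
}

#' Neighbour's-neighbours ablation sweep
#'
#' Convenience wrapper for [run_sweep()] restricted to the `"no_nn"`
#' condition: identical schema, with the diffuse second-ring signal disabled.
#'
#' @inheritParams run_sweep
#' @return A `cema_sweep`.
#' @export
run_ablation_no_nn <- function(cohort_sizes = c(1, 4, 9, 16, 25, 49, 100, 169, 256, 324),
                               replicates = NULL,
                               ci_level = 0.95,
                               config = sim_config(),
                               seed = 1L) {
  run_sweep(cohort_sizes = cohort_sizes, conditions = "no_nn",
            replicates = replicates, ci_level = ci_level,
            config = config, seed = seed)
}

#' @export
print.cema_sweep <- function(x, ...) {
  cat(sprintf("<cema_sweep> %d replicate rows, %d aggregate cells (seed %s)\n",
              nrow(x$replicates), nrow(x$summary), format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_sweep Replicate-level rows as a tibble.
#' @param x A `cema_sweep` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cema_sweep <- function(x, ...) {
  x$replicates
}

#' @describeIn run_sweep Aggregate rows (mean survival with confidence
#'   interval) as a tibble.
#' @exportS3Method generics::glance
glance.cema_sweep <- function(x, ...) {
  x$summary
}

#' Plot a survival sweep
#'
#' Mean survival per condition with confidence-interval bars, against cohort
#' size (or against noise probability for a noise sweep).
#'
#' @param object A `cema_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cema_sweep <- function(object, ...) {
  xvar <- if ("p_noise" %in% names(object$summary)) "p_noise" else "n"
  xlab <- if (xvar == "p_noise") "noise probability" else "cohort size"
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data[[xvar]], y = .data$mean,
                 colour = if ("condition" %in% names(object$summary))
                   .data$condition else NULL)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "mean survival", colour = "condition") +
    ggplot2::theme_minimal()
}
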