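sim_keys <- c("n", "p_noise", "n_dec", "theta", "w_self", "w_nb", "w_nn",
              "signaling", "nn_enabled", "locked_fraction", "replicates",
              "decrement", "exposure", "topology", "mix_snapshot",
              "broadcast_content", "support_scope", "support_scaling",
              "mix_participants", "locked_layout")
eca_keys <- c("length", "steps", "init_ones", "init_mode", "boundary")
sweep_keys <- c("cohort_sizes", "conditions", "replicates", "ci_level", "seed",
                "p_values", "n")
calcium_keys <- c("pixel_size", "frame_interval", "baseline_frames",
                  "injury_frame", "sustain_seconds", "injury_site", "rois",
                  "speed", "post_frames", "width", "height", "baseline_level",
                  "noise_sd", "flash_rate", "flash_amplitude", "flash_radius",
                  "flash_duration", "wave_amplitude", "wave_decay", "seed")

reject_unknown <- function(given, known, section) {
  extra <- setdiff(names(given), known)
  if (length(extra) > 0) {
    abort(sprintf("Unknown key%s in %s configuration: %s",
                  if (length(extra) > 1) "s" else "", section,
                  paste(extra, collapse = ", ")))
  }
}

#' Load a simulation / sweep / calcium configuration from YAML
#'
#' The file may contain up to three sections -- `simulation`, `sweep` and
#' `calcium` -- each a flat key-value map (the `simulation` section may nest
#' an `eca` map). Missing keys take the model defaults, so an empty file
#' yields the full default configuration; unknown keys and out-of-range
#' values are rejected with an error naming the offending key.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `simulation` (a [sim_config()]), `sweep`
#'   (a list of sweep arguments, possibly empty) and `calcium` (a list of
#'   calcium parameters, possibly empty).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  reject_unknown(raw, c("simulation", "sweep", "calcium"), "top-level")

  sim_raw <- raw$simulation %||% list()
  reject_unknown(sim_raw, c(sim_keys, "eca"), "simulation")
  eca_raw <- sim_raw$eca %||% list()
  reject_unknown(eca_raw, eca_keys, "simulation$eca")
  eca <- do.call(eca_config, eca_raw)
  sim_args <- sim_raw[setdiff(names(sim_raw), "eca")]
  simulation <- do.call(sim_config, c(sim_args, list(eca = eca)))

  sweep <- raw$sweep %||% list()
  reject_unknown(sweep, sweep_keys, "sweep")
  if (!is.null(sweep$cohort_sizes)) sweep$cohort_sizes <- unlist(sweep$cohort_sizes)
  if (!is.null(sweep$conditions)) sweep$conditions <- unlist(sweep$conditions)
  if (!is.null(sweep$p_values)) sweep$p_values <- unlist(sweep$p_values)

  calcium <- raw$calcium %||% list()
  reject_unknown(calcium, calcium_keys, "calcium")
  if (!is.null(calcium$rois)) {
    calcium$rois <- purrr::map_dfr(calcium$rois, function(r) {
      reject_unknown(r, c("x", "y", "radius", "label"), "calcium$rois")
      calcium_roi(r$x, r$y, r$radius, r$label %||% "roi")
    })
  }
  if (!is.null(calcium$injury_site)) calcium$injury_site <- unlist(calcium$injury_site)

  list(simulation = simulation, sweep = sweep, calcium = calcium)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration to YAML
#'
#' Writes a file that [load_config()] reads back to an identical
#' configuration.
#'
#' @param config A list as returned by [load_config()], or a single
#'   [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "sim_config")) config <- list(simulation = config)
  out <- list()
  if (!is.null(config$simulation)) {
    sim <- unclass(config$simulation)
    out$simulation <- c(sim[sim_keys], list(eca = unclass(sim$eca)))
  }
  if (length(config$sweep %||% list()) > 0) out$sweep <- config$sweep
  if (length(config$calcium %||% list()) > 0) {
    cal <- config$calcium
    if (!is.null(cal$rois)) {
      cal$rois <- purrr::pmap(cal$rois, function(x, y, radius, label) {
        list(x = x, y = y, radius = radius, label = label)
      })
    }
    if (!is.null(cal$injury_site)) cal$injury_site <- as.list(cal$injury_site)
    out$calcium <- cal
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build a run manifest
#'
#' Collects everything needed to trace a result file back to its run: the
#' complete configuration snapshot (including every interpretation switch),
#' the master seed, the package version, a timestamp and the output paths.
#'
#' @param command Name of the command or function that produced the outputs.
#' @param config A [sim_config()] or the list returned by [load_config()].
#' @param seed Master seed of the run.
#' @param outputs Character vector of output file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed, outputs = character()) {
  snapshot <- if (inherits(config, "sim_config")) {
    sim <- unclass(config)
    c(sim[sim_keys], list(eca = unclass(sim$eca)))
  } else {
    config
  }
  structure(
    list(command = command,
         config = snapshot,
         seed = seed,
         package = "cemasim",
         version = as.character(utils::packageVersion("cemasim")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = outputs),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write sweep results to tidy and aggregate CSV files
#'
#' @param sweep A `cema_sweep`.
#' @param replicates_path Path for the per-replicate CSV.
#' @param summary_path Path for the aggregate CSV.
#' @return The two paths, invisibly.
#' @export
write_sweep_csv <- function(sweep, replicates_path, summary_path) {
  stopifnot(inherits(sweep, "cema_sweep"))
  write.csv(sweep$replicates, replicates_path, row.names = FALSE)
  write.csv(sweep$summary, summary_path, row.names = FALSE)
  invisible(c(replicates_path, summary_path))
}
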