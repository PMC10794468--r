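#' Generate a synthetic calcium-imaging movie with known ground truth
#'
#' Builds a grayscale image stack emulating the injury assay: two (or more)
#' embryos in a channel, Gaussian baseline noise, sparse spontaneous calcium
#' flashes, and -- after the injury frame -- a radially expanding intensity
#' front that leaves the injury site at a known speed, sweeps the injured
#' embryo and crosses into the receiver. Pixels light up when the front
#' reaches them and decay exponentially afterwards, so receiver traces show a
#' sustained elevation rather than a blip. The returned ground truth makes the
#' movie usable as an end-to-end validation target for the analysis pipeline.
#'
#' Temporal defaults mirror the imaging protocol (2 s per frame, 10 min
#' baseline, 20 min post-injury); the spatial scale is set by `pixel_size`.
#'
#' @param speed True wave speed in micrometres per second.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds per frame.
#' @param baseline_frames Frames of spontaneous activity before the injury.
#' @param post_frames Frames recorded after the injury.
#' @param width,height Image size in pixels.
#' @param embryos Tibble with one row per embryo (`x`, `y`, `radius` in
#'   pixels, `label`); the defaults place an injured and a receiver embryo in
#'   a channel.
#' @param injury_site Numeric `c(x, y)` in pixels; defaults to the left edge
#'   of the first embryo.
#' @param baseline_level Mean baseline intensity (arbitrary units in
#'   `[0, 1]`).
#' @param noise_sd Standard deviation of the Gaussian pixel noise.
#' @param flash_rate Expected spontaneous flashes per embryo per frame.
#' @param flash_amplitude,flash_radius,flash_duration Intensity, radius
#'   (pixels) and duration (frames) of each spontaneous flash.
#' @param wave_amplitude Intensity added at the wave front.
#' @param wave_decay Exponential decay time of the wave signal, seconds.
#' @param injury If `FALSE`, no injury front is generated (spontaneous-only
#'   movie).
#' @param seed Optional seed; identical seeds give identical stacks.
#' @return An object of class `calcium_movie`: list with `stack`
#'   (height x width x frames array, values in `[0, 1]`), `rois` (the embryo
#'   table), `injury_site`, acquisition parameters, and `truth` (true speed,
#'   injury frame, and per-receiver distance and transfer time).
#' @export
synth_calcium_movie <- function(speed = 5,
                                pixel_size = 20,
                                frame_interval = 2,
                                baseline_frames = 300L,
                                post_frames = 600L,
                                width = 230L, height = 80L,
                                embryos = NULL,
                                injury_site = NULL,
                                baseline_level = 0.1,
                                noise_sd = 0.01,
                                flash_rate = 0.01,
                                flash_amplitude = 0.15,
                                flash_radius = 3,
                                flash_duration = 5L,
                                wave_amplitude = 0.5,
                                wave_decay = 180,
                                injury = TRUE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (speed <= 0) abort("`speed` must be positive.")
  if (is.null(embryos)) {
    embryos <- dplyr::bind_rows(
      calcium_roi(x = round(width * 0.26), y = round(height / 2),
                  radius = round(height * 0.38), label = "injured"),
      calcium_roi(x = round(width * 0.74), y = round(height / 2),
                  radius = round(height * 0.38), label = "receiver")
    )
  }
  if (is.null(injury_site)) {
    injury_site <- c(x = embryos$x[1] - embryos$radius[1], y = embryos$y[1])
  }
  n_frames <- baseline_frames + post_frames
  injury_frame <- baseline_frames

  cols <- matrix(rep(seq_len(width), each = height), height, width)
  rows <- matrix(rep(seq_len(height), times = width), height, width)
  mask <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(embryos))) {
    mask <- mask | ((cols - embryos$x[i])^2 + (rows - embryos$y[i])^2 <=
                      embryos$radius[i]^2)
  }
  # seconds after injury at which the front reaches each pixel
  dist_um <- sqrt((cols - injury_site[[1]])^2 + (rows - injury_site[[2]])^2) *
    pixel_size
  onset_s <- dist_um / speed

  # spontaneous flashes: per-embryo Poisson events across the whole movie
  flashes <- list()
  for (i in seq_len(nrow(embryos))) {
    k <- rpois(1, flash_rate * n_frames)
    if (k == 0) next
    ang <- runif(k, 0, 2 * pi)
    rad <- embryos$radius[i] * sqrt(runif(k))
    flashes[[i]] <- tibble(
      x = embryos$x[i] + rad * cos(ang),
      y = embryos$y[i] + rad * sin(ang),
      start = sample.int(n_frames, k, replace = TRUE)
    )
  }
  flashes <- bind_rows(flashes)

  stack <- array(0, dim = c(height, width, n_frames))
  for (f in seq_len(n_frames)) {
    img <- baseline_level +
      matrix(rnorm(height * width, 0, noise_sd), height, width)
    if (nrow(flashes) > 0) {
      active <- flashes[flashes$start <= f & f < flashes$start + flash_duration, ]
      for (j in seq_len(nrow(active))) {
        hitpx <- (cols - active$x[j])^2 + (rows - active$y[j])^2 <= flash_radius^2
        img[hitpx] <- img[hitpx] + flash_amplitude
      }
    }
    if (injury && f > injury_frame) {
      t_post <- (f - injury_frame) * frame_interval
      lit <- mask & (onset_s <= t_post)
      if (any(lit)) {
        img[lit] <- img[lit] +
          wave_amplitude * exp(-(t_post - onset_s[lit]) / wave_decay)
      }
    }
    stack[, , f] <- pmin(1, pmax(0, img))
  }

  receivers <- embryos[embryos$label != "injured", , drop = FALSE]
  truth_rows <- purrr::map_dfr(seq_len(nrow(receivers)), function(i) {
    d <- injury_distance(injury_site, receivers[i, ], pixel_size)
    tibble(label = receivers$label[i], distance_um = d,
           transfer_time = if (injury) d / speed else NA_real_)
  })

  structure(
    list(stack = stack, rois = embryos, injury_site = injury_site,
         pixel_size = pixel_size, frame_interval = frame_interval,
         baseline_frames = baseline_frames, injury_frame = injury_frame,
         truth = list(speed = if (injury) speed else NA_real_,
                      injury_frame = injury_frame, receivers = truth_rows)),
    class = "calcium_movie"
  )
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<calcium_movie> %dx%d px, %d frames (%d baseline), true speed %s um/s\n",
              d[2], d[1], d[3], x$baseline_frames, format(x$truth$speed)))
  invisible(x)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' @param path Path to a TIFF file.
#' @return Numeric array `height x width x frames` with values in `[0, 1]`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3L) f[, , 1] else f)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write an image stack to a multi-frame grayscale TIFF
#'
#' Values are clamped to `[0, 1]` and stored as 16-bit samples.
#'
#' @param stack Numeric array `height x width x frames`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (length(dim(stack)) != 3L) abort("`stack` must be a 3-d array (h x w x frames).")
  stack[stack < 0] <- 0
  stack[stack > 1] <- 1
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}
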