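#' Fluorescence trace for one region of interest
#'
#' A per-frame mean-intensity time series with its acquisition metadata. The
#' default frame interval (2 s) and baseline window (300 frames = 10 min of
#' spontaneous activity recorded before injury) follow the imaging protocol
#' the quantification is designed for.
#'
#' @param values Numeric vector of per-frame mean gray values (non-negative).
#' @param frame_interval Seconds per frame.
#' @param baseline_frames Number of pre-injury frames forming the baseline
#'   window.
#' @param normalized Whether `values` are already fold-changes over the
#'   baseline mean.
#' @return An object of class `fl_trace`.
#' @export
fl_trace <- function(values, frame_interval = 2, baseline_frames = 300,
                     normalized = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("Trace values must be finite and non-negative.")
  }
  if (frame_interval <= 0) abort("`frame_interval` must be positive.")
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L || baseline_frames >= length(values)) {
    abort("`baseline_frames` must be >= 1 and smaller than the trace length.")
  }
  structure(
    list(values = values, frame_interval = frame_interval,
         baseline_frames = baseline_frames, normalized = isTRUE(normalized)),
    class = "fl_trace"
  )
}

#' @export
print.fl_trace <- function(x, ...) {
  cat(sprintf("<fl_trace> %d frames @ %gs, %d baseline frames%s\n",
              length(x$values), x$frame_interval, x$baseline_frames,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @describeIn fl_trace Frame-indexed tibble (`frame`, `time_s`, `value`).
#' @param x An `fl_trace`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fl_trace <- function(x, ...) {
  tibble(
    frame = seq_along(x$values),
    time_s = (seq_along(x$values) - 1) * x$frame_interval,
    value = x$values
  )
}

#' Circular region of interest
#'
#' @param x,y Centre in pixel coordinates (x = column, y = row).
#' @param radius Radius in pixels.
#' @param label Free-text label, conventionally `"injured"` or `"receiver"`.
#' @return A one-row tibble.
#' @export
calcium_roi <- function(x, y, radius, label = "roi") {
  if (radius <= 0) abort("`radius` must be positive.")
  tibble(x = x, y = y, radius = radius, label = label)
}

roi_pixels <- function(stack_dim, roi) {
  h <- stack_dim[1]; w <- stack_dim[2]
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  inside <- (cols - roi$x)^2 + (rows - roi$y)^2 <= roi$radius^2
  if (!any(inside)) abort("ROI covers no pixels of the image.")
  which(inside)
}

#' Extract the mean-intensity trace of a circular ROI from an image stack
#'
#' @param stack Numeric array `height x width x frames`.
#' @param roi A [calcium_roi()] row (or any list with `x`, `y`, `radius`).
#' @param frame_interval Seconds per frame.
#' @param baseline_frames Pre-injury frames in the baseline window.
#' @return An [fl_trace()] of per-frame means over the pixels inside the
#'   circle.
#' @export
extract_trace <- function(stack, roi, frame_interval = 2,
                          baseline_frames = 300) {
  if (length(dim(stack)) != 3L) abort("`stack` must be a 3-d array (h x w x frames).")
  if (roi$x - roi$radius < 1 || roi$x + roi$radius > dim(stack)[2] ||
      roi$y - roi$radius < 1 || roi$y + roi$radius > dim(stack)[1]) {
    abort("ROI extends beyond the image bounds.")
  }
  px <- roi_pixels(dim(stack), roi)
  n_frames <- dim(stack)[3]
  flat <- matrix(stack, ncol = n_frames)
  fl_trace(colMeans(flat[px, , drop = FALSE]),
           frame_interval = frame_interval,
           baseline_frames = baseline_frames)
}

#' Normalize a trace to its baseline mean
#'
#' Divides every value by the mean of the baseline window, so the baseline
#' mean of the output is exactly 1 and values read as fold-change over
#' spontaneous activity.
#'
#' @param trace An [fl_trace()].
#' @return A normalized `fl_trace`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fl_trace"))
  b <- mean(trace$values[seq_len(trace$baseline_frames)])
  if (b <= 0) abort("Baseline mean is zero; cannot normalize.")
  fl_trace(trace$values / b, trace$frame_interval, trace$baseline_frames,
           normalized = TRUE)
}

#' Detect a sustained injury-wave transfer in a normalized trace
#'
#' The detection threshold is the maximum of the normalized baseline window
#' (the peak of spontaneous activity). A transfer is called at the first
#' post-injury frame whose value exceeds the threshold and stays above it
#' continuously for more than `sustain_seconds` (brief supra-threshold blips
#' are rejected; a dip below threshold resets the clock). Absence of a
#' transfer is a valid result, not an error.
#'
#' @param trace A normalized [fl_trace()].
#' @param injury_frame Frame index at which injury was induced (>= the
#'   baseline window).
#' @param sustain_seconds Minimum continuous supra-threshold duration.
#' @return An object of class `wave_event` with fields `detected`,
#'   `transfer_frame`, `transfer_time` (seconds from injury), `peak` (maximum
#'   normalized post-injury signal) and `threshold`.
#' @export
detect_transfer <- function(trace, injury_frame = trace$baseline_frames,
                            sustain_seconds = 60) {
  stopifnot(inherits(trace, "fl_trace"))
  if (!trace$normalized) abort("`trace` must be normalized first (see normalize_trace()).")
  if (injury_frame < trace$baseline_frames) {
    abort("`injury_frame` must not precede the baseline window.")
  }
  v <- trace$values
  threshold <- max(v[seq_len(trace$baseline_frames)])
  post <- v[(injury_frame + 1L):length(v)]
  peak <- max(post)
  above <- post > threshold
  need <- floor(sustain_seconds / trace$frame_interval) + 1L
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= need)
  event <- list(detected = FALSE, transfer_frame = NA_integer_,
                transfer_time = NA_real_, peak = peak, threshold = threshold,
                frame_interval = trace$frame_interval)
  if (length(ok) > 0) {
    first <- starts[ok[1]]
    event$detected <- TRUE
    event$transfer_frame <- injury_frame + first
    event$transfer_time <- first * trace$frame_interval
  }
  structure(event, class = "wave_event")
}

#' @export
print.wave_event <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<wave_event> transfer at %.0f s (frame %d), peak %.3f, threshold %.3f\n",
                x$transfer_time, x$transfer_frame, x$peak, x$threshold))
  } else {
    cat(sprintf("<wave_event> no sustained transfer (peak %.3f vs threshold %.3f)\n",
                x$peak, x$threshold))
  }
  invisible(x)
}

#' @describeIn detect_transfer One-row tibble of the event.
#' @param x A `wave_event`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wave_event <- function(x, ...) {
  tibble(detected = x$detected, transfer_frame = x$transfer_frame,
         transfer_time = x$transfer_time, peak = x$peak,
         threshold = x$threshold)
}

#' Distance from the injury site to the nearest point of a receiver ROI
#'
#' @param injury_site Numeric `c(x, y)` in pixels.
#' @param roi Receiver [calcium_roi()].
#' @param pixel_size Micrometres per pixel.
#' @return Distance in micrometres (0 when the site touches the circle).
#' @export
injury_distance <- function(injury_site, roi, pixel_size) {
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  d <- sqrt((injury_site[[1]] - roi$x)^2 + (injury_site[[2]] - roi$y)^2)
  max(0, d - roi$radius) * pixel_size
}

#' Inter-embryo wave speed from a detected transfer
#'
#' Speed is the injury-site-to-receiver distance (vector magnitude to the
#' closest point of the receiver ROI) divided by the transfer time.
#'
#' @param event A detected `wave_event`.
#' @param injury_site Numeric `c(x, y)` in pixels.
#' @param receiver_roi Receiver [calcium_roi()].
#' @param pixel_size Micrometres per pixel.
#' @return Speed in micrometres per second.
#' @export
inter_embryo_speed <- function(event, injury_site, receiver_roi, pixel_size) {
  stopifnot(inherits(event, "wave_event"))
  if (!event$detected) abort("No transfer was detected; speed is undefined.")
  injury_distance(injury_site, receiver_roi, pixel_size) / event$transfer_time
}

#' Cell-to-cell wave speed from peak-to-peak delay
#'
#' Uses the global intensity maxima of two traces sampled on the same frame
#' grid: the delay is the difference of their argmax times, and speed is
#' distance over delay.
#'
#' @param trace_start,trace_end Normalized [fl_trace()]s at the start and end
#'   of the wave path.
#' @param distance_um Distance between the two sampling sites in micrometres.
#' @return Speed in micrometres per second.
#' @examples
#' a <- fl_trace(c(rep(1, 5), 3, rep(1, 44)), baseline_frames = 4)
#' b <- fl_trace(c(rep(1, 25), 3, rep(1, 24)), baseline_frames = 4)
#' cell_to_cell_speed(a, b, distance_um = 200) # 200 / (20 frames * 2 s)
#' @export
cell_to_cell_speed <- function(trace_start, trace_end, distance_um) {
  stopifnot(inherits(trace_start, "fl_trace"), inherits(trace_end, "fl_trace"))
  if (length(trace_start$values) != length(trace_end$values) ||
      trace_start$frame_interval != trace_end$frame_interval) {
    abort("Traces must share the same frame grid.")
  }
  delay <- (which.max(trace_end$values) - which.max(trace_start$values)) *
    trace_start$frame_interval
  if (delay <= 0) abort("Peak-to-peak delay is not positive; wave direction violated.")
  distance_um / delay
}

#' Kymograph along a line through the stack
#'
#' Samples the intensity profile along the segment from `from` to `to`
#' (nearest-pixel sampling) in every frame; each column of the result is one
#' frame, so a front moving at constant speed appears as a sloped band.
#'
#' @param stack Numeric array `height x width x frames`.
#' @param from,to Numeric `c(x, y)` segment endpoints in pixels.
#' @param n_positions Number of sample positions (defaults to the segment
#'   length in pixels).
#' @return A `kymograph`: numeric matrix `n_positions x n_frames` with the
#'   sampling geometry in attributes.
#' @export
make_kymograph <- function(stack, from, to, n_positions = NULL) {
  if (length(dim(stack)) != 3L) abort("`stack` must be a 3-d array (h x w x frames).")
  seg_len <- sqrt((to[[1]] - from[[1]])^2 + (to[[2]] - from[[2]])^2)
  if (is.null(n_positions)) n_positions <- max(2L, as.integer(round(seg_len)) + 1L)
  s <- seq(0, 1, length.out = n_positions)
  xs <- round(from[[1]] + s * (to[[1]] - from[[1]]))
  ys <- round(from[[2]] + s * (to[[2]] - from[[2]]))
  if (any(xs < 1 | xs > dim(stack)[2] | ys < 1 | ys > dim(stack)[1])) {
    abort("Sampling segment extends beyond the image bounds.")
  }
  n_frames <- dim(stack)[3]
  flat <- matrix(stack, ncol = n_frames)
  px <- (xs - 1L) * dim(stack)[1] + ys
  out <- flat[px, , drop = FALSE]
  structure(out, class = c("kymograph", "matrix"),
            from = c(from[[1]], from[[2]]), to = c(to[[1]], to[[2]]))
}

#' @rdname make_kymograph
#' @param object A `kymograph`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(position = seq_len(nrow(object)),
                           frame = seq_len(ncol(object)))
  df$intensity <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$position,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = "position along line") +
    ggplot2::theme_minimal()
}

#' Full calcium analysis of a stack with labelled ROIs
#'
#' Extracts and normalizes one trace per ROI, runs sustained-transfer
#' detection on every ROI and derives the inter-embryo speed for receiver
#' ROIs from the injury-site geometry.
#'
#' @param stack Numeric array `height x width x frames`.
#' @param rois Tibble of [calcium_roi()] rows (labels `"injured"` /
#'   `"receiver"` by convention).
#' @param injury_site Numeric `c(x, y)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds per frame.
#' @param baseline_frames Baseline window length in frames.
#' @param injury_frame Injury frame (defaults to the end of the baseline
#'   window).
#' @param sustain_seconds Sustain requirement for transfer detection.
#' @return A list with `traces` (long tibble: `label`, `frame`, `time_s`,
#'   `raw`, `normalized`) and `events` (one row per ROI: detection, transfer
#'   time, peak, threshold, distance and speed).
#' @export
analyze_calcium <- function(stack, rois, injury_site, pixel_size,
                            frame_interval = 2, baseline_frames = 300,
                            injury_frame = baseline_frames,
                            sustain_seconds = 60) {
  traces <- list()
  events <- list()
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    raw <- extract_trace(stack, roi, frame_interval, baseline_frames)
    norm <- normalize_trace(raw)
    traces[[i]] <- tibble(
      label = roi$label,
      frame = seq_along(raw$values),
      time_s = (seq_along(raw$values) - 1) * frame_interval,
      raw = raw$values,
      normalized = norm$values
    )
    ev <- detect_transfer(norm, injury_frame, sustain_seconds)
    row <- tidy(ev)
    row$label <- roi$label
    row$distance_um <- injury_distance(injury_site, roi, pixel_size)
    row$speed_um_s <- if (ev$detected && row$distance_um > 0) {
      row$distance_um / ev$transfer_time
    } else if (ev$detected) 0 else NA_real_
    events[[i]] <- row
  }
  list(
    traces = bind_rows(traces),
    events = bind_rows(events) |>
      select("label", "detected", "transfer_frame", "transfer_time",
             "peak", "threshold", "distance_um", "speed_um_s")
  )
}
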