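small_movie <- function(speed = 5, seed = 1, injury = TRUE,
                        post_frames = 300, flash_rate = 0.01) {
  synth_calcium_movie(
    speed = speed, width = 120, height = 50, pixel_size = 20,
    baseline_frames = 60, post_frames = post_frames,
    flash_rate = flash_rate, injury = injury, seed = seed
  )
}

test_that("trace extraction recovers known per-frame ROI means", {
  stack <- array(0.25, dim = c(20, 30, 8))
  roi <- calcium_roi(x = 15, y = 10, radius = 4)
  tr <- extract_trace(stack, roi, baseline_frames = 4)
  expect_equal(tr$values, rep(0.25, 8))
  # single-pixel ROI returns that pixel's series
  stack[5, 7, ] <- seq(0.1, 0.8, length.out = 8)
  one <- extract_trace(stack, calcium_roi(7, 5, radius = 0.5),
                       baseline_frames = 4)
  expect_equal(one$values, seq(0.1, 0.8, length.out = 8))
  expect_error(extract_trace(stack, calcium_roi(2, 2, radius = 5)), "bounds")
})

test_that("normalization yields baseline mean one and is scale invariant", {
  raw <- fl_trace(c(rep(100, 10), rep(120, 5), 177), baseline_frames = 10)
  nm <- normalize_trace(raw)
  expect_equal(mean(nm$values[1:10]), 1, tolerance = 1e-9)
  expect_equal(max(nm$values), 1.77)
  scaled <- normalize_trace(fl_trace(raw$values * 7, baseline_frames = 10))
  expect_equal(nm$values, scaled$values, tolerance = 1e-12)
  const <- normalize_trace(fl_trace(rep(5, 20), baseline_frames = 8))
  expect_equal(const$values, rep(1, 20))
  expect_error(normalize_trace(fl_trace(c(0, 0, 1), baseline_frames = 2)),
               "Baseline")
})

test_that("transfer detection applies the one-minute sustain rule", {
  base <- rep(1, 300)
  # sustained step to 2x baseline 120 frames after injury -> 240 s at 2 s/frame
  v <- c(base, rep(1, 119), rep(2, 481))
  tr <- fl_trace(v, baseline_frames = 300, normalized = TRUE)
  ev <- detect_transfer(tr, injury_frame = 300)
  expect_true(ev$detected)
  expect_equal(ev$transfer_time, 240)
  expect_equal(ev$peak, 2)

  # a 30 s supra-threshold blip (15 frames) is rejected
  blip <- c(base, rep(1, 119), rep(2, 15), rep(1, 466))
  evb <- detect_transfer(fl_trace(blip, baseline_frames = 300,
                                  normalized = TRUE), injury_frame = 300)
  expect_false(evb$detected)

  # never exceeding the baseline maximum -> absent
  flat <- detect_transfer(fl_trace(rep(1, 900), baseline_frames = 300,
                                   normalized = TRUE), injury_frame = 300)
  expect_false(flat$detected)
  expect_error(detect_transfer(fl_trace(rep(1, 10), baseline_frames = 5),
                               injury_frame = 5), "normalized")
})

test_that("raising the spontaneous maximum can only delay or abolish detection", {
  set.seed(6)
  for (k in 1:10) {
    post <- 1 + cumsum(runif(200, -0.05, 0.07))
    v1 <- c(rep(1, 50), pmax(post, 0))
    v2 <- v1
    v2[25] <- 1.5 # a higher spontaneous peak raises the threshold
    e1 <- detect_transfer(fl_trace(v1, baseline_frames = 50,
                                   normalized = TRUE), injury_frame = 50,
                          sustain_seconds = 20)
    e2 <- detect_transfer(fl_trace(v2, baseline_frames = 50,
                                   normalized = TRUE), injury_frame = 50,
                          sustain_seconds = 20)
    if (e2$detected) {
      expect_true(e1$detected)
      expect_gte(e2$transfer_time, e1$transfer_time)
    }
  }
})

test_that("speed arithmetic matches the distance and delay definitions", {
  v <- c(rep(1, 300), rep(1, 119), rep(2, 481))
  ev <- detect_transfer(fl_trace(v, baseline_frames = 300, normalized = TRUE),
                        injury_frame = 300)
  roi <- calcium_roi(x = 100, y = 10, radius = 40)
  # centre distance 100 px, radius 40 px -> 60 px; at 20 um/px -> 1200 um
  expect_equal(inter_embryo_speed(ev, c(0, 10), roi, pixel_size = 20),
               1200 / 240)
  # injury site touching the ROI boundary -> distance and speed zero
  expect_equal(inter_embryo_speed(ev, c(60, 10), roi, pixel_size = 20), 0)
  absent <- detect_transfer(fl_trace(rep(1, 900), baseline_frames = 300,
                                     normalized = TRUE), injury_frame = 300)
  expect_error(inter_embryo_speed(absent, c(0, 10), roi, 20), "No transfer")

  a <- fl_trace(c(rep(1, 10), 3, rep(1, 89)), baseline_frames = 5,
                normalized = TRUE)
  b <- fl_trace(c(rep(1, 50), 3, rep(1, 49)), baseline_frames = 5,
                normalized = TRUE)
  expect_equal(cell_to_cell_speed(a, b, 536), 536 / 80) # 40 frames * 2 s
  expect_equal(cell_to_cell_speed(a, b, 1072), 2 * 536 / 80)
  expect_error(cell_to_cell_speed(a, a, 100), "delay")
})

test_that("kymographs have position-by-frame shape and flag moving fronts", {
  static <- array(rep(matrix(runif(20 * 30), 20, 30), 5), dim = c(20, 30, 5))
  ky <- make_kymograph(static, from = c(1, 10), to = c(30, 10))
  expect_equal(dim(ky), c(30, 5))
  expect_true(all(apply(ky, 1, function(r) all(r == r[1]))))

  mv <- small_movie(speed = 5, seed = 3)
  ky2 <- make_kymograph(mv$stack, mv$injury_site,
                        c(mv$rois$x[2], mv$rois$y[2]), n_positions = 60)
  expect_equal(ncol(ky2), dim(mv$stack)[3])
  # onset frame along the line advances with position: estimate the speed
  amp_mid <- 0.1 + 0.25
  pos_px <- seq(0, 1, length.out = 60) *
    sqrt(sum((c(mv$rois$x[2], mv$rois$y[2]) - mv$injury_site)^2))
  onset <- apply(ky2 > amp_mid, 1, function(r) which(r)[1])
  sel <- which(!is.na(onset) & onset > mv$injury_frame + 2)
  fit <- coef(lm(I(pos_px[sel] * 20) ~ I((onset[sel] - mv$injury_frame) * 2)))
  expect_equal(unname(fit[2]), 5, tolerance = 0.1)
})

test_that("the synthetic generator is deterministic and controllable", {
  a <- small_movie(seed = 11)
  b <- small_movie(seed = 11)
  expect_identical(a$stack, b$stack)
  quiet <- synth_calcium_movie(width = 60, height = 30, baseline_frames = 20,
                               post_frames = 10, noise_sd = 0, flash_rate = 0,
                               injury = TRUE, seed = 1)
  pre <- quiet$stack[, , 1:20]
  expect_true(all(pre == pre[1, 1, 1])) # flat baseline before injury
})

test_that("spontaneous-only movies rarely produce a sustained transfer", {
  detected <- vapply(1:6, function(s) {
    mv <- small_movie(seed = s, injury = FALSE, post_frames = 150)
    roi <- mv$rois[mv$rois$label == "receiver", ]
    tr <- normalize_trace(extract_trace(mv$stack, roi,
                                        baseline_frames = mv$baseline_frames))
    detect_transfer(tr, injury_frame = mv$injury_frame)$detected
  }, logical(1))
  expect_lte(sum(detected), 1)
})

test_that("the pipeline recovers a known wave speed end to end", {
  for (s in 1:2) {
    mv <- small_movie(speed = 5, seed = s)
    res <- analyze_calcium(mv$stack, mv$rois, mv$injury_site, mv$pixel_size,
                           baseline_frames = mv$baseline_frames,
                           injury_frame = mv$injury_frame)
    rec <- res$events$speed_um_s[res$events$label == "receiver"]
    expect_equal(rec, 5, tolerance = 0.1)
  }
})

test_that("TIFF stacks round-trip through disk", {
  mv <- synth_calcium_movie(width = 40, height = 24, baseline_frames = 10,
                            post_frames = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(mv$stack, path)
  back <- read_image_stack(path)
  expect_equal(dim(back), dim(mv$stack))
  expect_lt(max(abs(back - mv$stack)), 2 / 65535) # 16-bit quantisation
})
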