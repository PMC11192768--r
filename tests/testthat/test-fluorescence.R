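test_that("ROI integration equals a brute-force double-loop sum", {
  set.seed(11)
  frames <- array(runif(16 * 16 * 6), dim = c(16, 16, 6))
  optics <- optics_config(frame_px = c(16, 16),
                          roi = list(x = 3, y = 5, width = 7, height = 4))
  tr <- integrate_roi(frames, optics)
  for (f in 1:6) {
    acc <- 0
    for (r in 5:8) for (cc in 3:9) acc <- acc + frames[r, cc, f]
    expect_equal(tr$intensity[f], acc)
  }
  expect_equal(tr$t_s, (1:6 - 0.5) / optics$frame_rate_hz)
})

test_that("ROI integration handles degenerate frames and is linear", {
  optics <- optics_config(frame_px = c(12, 12),
                          roi = list(x = 2, y = 2, width = 10, height = 10))
  ones <- array(1, dim = c(12, 12, 3))
  expect_equal(integrate_roi(ones, optics)$intensity, rep(100, 3))
  zeros <- array(0, dim = c(12, 12, 3))
  expect_equal(integrate_roi(zeros, optics)$intensity, rep(0, 3))

  set.seed(22)
  f1 <- array(runif(12 * 12 * 4), dim = c(12, 12, 4))
  f2 <- array(runif(12 * 12 * 4), dim = c(12, 12, 4))
  a <- 2.5; b <- 0.7
  expect_equal(integrate_roi(a * f1 + b * f2, optics)$intensity,
               a * integrate_roi(f1, optics)$intensity +
               b * integrate_roi(f2, optics)$intensity)

  bad <- optics_config(frame_px = c(32, 32),
                       roi = list(x = 1, y = 1, width = 16, height = 8))
  expect_error(integrate_roi(array(0, c(8, 8, 2)), bad), "ROI")
})

test_that("noiseless video: zero particles give a flat trace, one particle one peak", {
  optics <- optics_config()
  v0 <- generate_video(video_spec(duration_s = 0.1, n_particles = 0,
                                  noise_model = "none", seed = 1), optics)
  expect_true(all(v0$frames == v0$frames[1, 1, 1]))
  tr0 <- integrate_roi(v0)
  expect_equal(diff(range(tr0$intensity)), 0)

  v1 <- generate_video(video_spec(duration_s = 0.1, n_particles = 1,
                                  transit_times_s = 0.05,
                                  noise_model = "none", seed = 1), optics)
  tr1 <- integrate_roi(v1)
  peak_t <- tr1$t_s[which.max(tr1$intensity)]
  expect_lt(abs(peak_t - 0.05), 1 / optics$frame_rate_hz)
})

test_that("the generator is deterministic for a fixed seed", {
  spec <- video_spec(duration_s = 0.2, n_particles = 5, seed = 99)
  v1 <- generate_video(spec)
  v2 <- generate_video(spec)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth, v2$truth)
  v3 <- generate_video(video_spec(duration_s = 0.2, n_particles = 5, seed = 100))
  expect_false(identical(v1$frames, v3$frames))
})

test_that("an infeasible spec (shorter than one event window) errors", {
  expect_error(
    generate_video(video_spec(duration_s = 0.001, n_particles = 0)),
    "shorter than one event window")
})

test_that("a single injected peak is detected exactly once at its frame", {
  rate <- 2000
  x <- rep(100, 400)
  x[200] <- 500
  tr <- fluor_trace((1:400 - 0.5) / rate, x + rnorm(400, 0, 1), rate)
  ev <- detect_events(tr, threshold_k = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 200)

  flat <- fluor_trace((1:400 - 0.5) / rate, rep(100, 400), rate)
  expect_equal(nrow(detect_events(flat, threshold_k = 5)), 0)
})

test_that("detection is invariant to a constant trace offset", {
  set.seed(33)
  vid <- generate_video(video_spec(duration_s = 0.5, n_particles = 20, seed = 7))
  tr <- integrate_roi(vid)
  ev0 <- detect_events(tr)
  tr_off <- fluor_trace(tr$t_s, tr$intensity + 12345,
                        attr(tr, "frame_rate_hz"))
  ev1 <- detect_events(tr_off)
  expect_equal(ev1$frame, ev0$frame)
  expect_equal(ev1$snr, ev0$snr)
})

test_that("raising the threshold never increases the event count", {
  vid <- generate_video(video_spec(duration_s = 0.5, n_particles = 20,
                                   amplitude_sdlog = 0.5, seed = 8))
  tr <- integrate_roi(vid)
  counts <- vapply(c(1, 2, 3, 5, 8, 13, 21, 50),
                   function(k) nrow(detect_events(tr, threshold_k = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("high-SNR synthetic video is recovered with near-perfect recall/precision", {
  vid <- generate_video(video_spec(seed = 2026))   # 100 particles, defaults
  expect_gte(vid$spec$amplitude / sqrt(vid$spec$background_level * 16 * 8), 10)
  tr <- integrate_roi(vid)
  ev <- detect_events(tr)
  m <- match_events(ev, vid$truth$t_s, tol_s = 0.005)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("event windows span round(window_ms * rate / 1000) frames and truncate at edges", {
  rate <- 2000
  optics <- optics_config(frame_rate_hz = rate, event_window_ms = 5)
  x <- rep(10, 300); x[150] <- 1000; x[2] <- 1000
  tr <- fluor_trace((1:300 - 0.5) / rate, x + rnorm(300, 0, 0.5), rate)
  ev <- detect_events(tr, threshold_k = 5, optics = optics)
  expect_equal(nrow(ev), 2)
  mid <- ev[ev$frame == 150, ]
  expect_equal(mid$window_end - mid$window_start + 1, 10)  # 0.005 s x 2000 fps
  expect_false(mid$truncated)
  edge <- ev[ev$frame == 2, ]
  expect_true(edge$truncated)
  expect_equal(edge$window_start, 1)

  segs <- crop_windows(tr, ev)
  expect_length(segs, 2)
  expect_equal(nrow(segs[[which(ev$frame == 150)]]), 10)
  expect_true(attr(segs[[which(ev$frame == 2)]], "truncated"))
  seg <- segs[[which(ev$frame == 150)]]
  expect_equal(seg$t_s, tr$t_s[mid$window_start:mid$window_end])
})

test_that("frame stacks and traces round-trip through TIFF and text files", {
  vid <- generate_video(video_spec(duration_s = 0.05, n_particles = 2, seed = 3))
  tif <- withr::local_tempfile(fileext = ".tif")
  write_frames_tiff(vid, tif)
  back <- read_frames_tiff(tif)
  expect_equal(dim(back), dim(vid$frames))
  expect_equal(back, vid$frames, tolerance = 1e-6)

  tr <- integrate_roi(vid)
  txt <- withr::local_tempfile(fileext = ".tsv")
  write_trace_txt(tr, txt)
  tr2 <- read_trace_txt(txt)
  expect_equal(tr2$intensity, tr$intensity)
  expect_equal(attr(tr2, "frame_rate_hz"), attr(tr, "frame_rate_hz"),
               tolerance = 1e-6)
})
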