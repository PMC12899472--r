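test_that("frame differencing is absolute, min-max normalised, degeneracy-flagged", {
  f1 <- matrix(0, 4, 4)
  f2 <- f1; f2[2, 3] <- 0.5
  clip <- video_clip(array(c(f1, f2), c(4, 4, 2)), fps = 30)
  d <- frame_difference(clip)
  expect_false(d$degenerate)
  expect_equal(d$values[2, 3, 1], 1)           # (0.5 - 0) / (0.5 - 0)
  expect_equal(sum(d$values), 1)

  same <- video_clip(array(0.3, c(4, 4, 3)), fps = 30)
  ds <- frame_difference(same)
  expect_true(all(ds$degenerate))
  expect_true(all(ds$values == 0))

  # |a - b| symmetry: reversing frame order gives identical differences
  clip_rev <- video_clip(array(c(f2, f1), c(4, 4, 2)), fps = 30)
  expect_equal(frame_difference(clip_rev)$values, d$values)
})

test_that("centre of mass matches hand calculation and brute-force oracle", {
  # rows: y, columns: x; row 0 holds 1 (x=0) and 3 (x=1)
  v <- matrix(c(1, 0, 3, 0), 2, 2)
  expect_equal(center_of_mass(v), c(xc = 0.75, yc = 0))
  u <- matrix(1, 5, 7)
  expect_equal(center_of_mass(u), c(xc = 3, yc = 2))   # geometric centre (W-1)/2, (H-1)/2
  s <- matrix(0, 9, 8); s[8, 4] <- 0.2                  # single pixel at x=3, y=7
  expect_equal(center_of_mass(s), c(xc = 3, yc = 7))
  expect_error(center_of_mass(matrix(0, 3, 3)), class = "tremorcam_error_degenerate")

  set.seed(11)
  for (i in 1:50) {
    m <- matrix(runif(12 * 9), 9, 12)
    expect_equal(center_of_mass(m), com_bruteforce(m), tolerance = 1e-12)
  }
})

test_that("centroids stay inside the RoI box and respect translation", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(64), 8, 8)
    cm <- center_of_mass(m)
    expect_gte(cm["xc"], 0); expect_lt(cm["xc"], 8)
    expect_gte(cm["yc"], 0); expect_lt(cm["yc"], 8)
  }
  # shifting scene content and RoI together leaves RoI-local centroids unchanged,
  # i.e. centroids are equivariant under translation
  scene <- single_blob_scene(5, seed = 2, duration_s = 2, noise_sd = 0.01)
  f <- scene$clip$frames
  dx <- 4L; dy <- 3L
  g <- array(0, dim(f))
  g[(1 + dy):dim(f)[1], (1 + dx):dim(f)[2], ] <-
    f[1:(dim(f)[1] - dy), 1:(dim(f)[2] - dx), ]
  shifted <- video_clip(g, fps = 30)
  tr1 <- com_trace(scene$clip, roi("a", 12, 10, 40, 40))
  tr2 <- com_trace(shifted, roi("a", 12 + dx, 10 + dy, 40, 40))
  expect_equal(tr2$xc, tr1$xc, tolerance = 1e-12)
  expect_equal(tr2$yc, tr1$yc, tolerance = 1e-12)
})

test_that("com_trace handles static scenes, lengths, and global intensity scaling", {
  static <- video_clip(array(0.4, c(10, 12, 30)), fps = 30)
  tr <- com_trace(static)
  expect_equal(nrow(tr), 29)
  expect_true(all(tr$degenerate))
  expect_true(all(tr$xc == (12 - 1) / 2) && all(tr$yc == (10 - 1) / 2))

  scene <- single_blob_scene(6, seed = 4, noise_sd = 0)
  expect_equal(nrow(com_trace(scene$clip)), 600 - 1)

  # per-pair min-max normalisation cancels a global intensity scale
  tr1 <- com_trace(scene$clip)
  scaled <- video_clip(scene$clip$frames * 0.35, fps = 30)
  tr2 <- com_trace(scaled)
  expect_equal(tr2$xc, tr1$xc, tolerance = 1e-9)
  expect_equal(tr2$yc, tr1$yc, tolerance = 1e-9)
})

test_that("an oscillating blob drives xc at the blob frequency, yc stays flat", {
  scene <- single_blob_scene(6, amp_px = 4, seed = 8, noise_sd = 0.005)
  tr <- com_trace(scene$clip, single_blob_roi())
  expect_equal(dominant_freq(tr$xc, attr(tr, "fs")), 6, tolerance = 30 / 599)
  expect_lt(stats::sd(tr$yc), stats::sd(tr$xc) / 4)
})

test_that("time-domain L1 centring removes offsets and rectifies to 2f", {
  static <- video_clip(array(0.4, c(10, 10, 20)), fps = 30)
  expect_true(all(l1_combine_time(com_trace(static))$value == 0))

  # build a trace directly: xc sinusoid about an offset, yc constant
  n <- 600; fs <- 30; f <- 4
  tr <- tibble::tibble(frame_index = 2:(n + 1), time_s = (1:n) / fs,
                       xc = 20 + 3 * sin(2 * pi * f * (1:n) / fs),
                       yc = rep(7, n), degenerate = FALSE)
  tr <- structure(tr, fs = fs, roi_label = "x", roi_width = 41, roi_height = 15,
                  class = c("motion_trace", class(tr)))
  sig <- l1_combine_time(tr)
  expect_equal(sig$value, abs(3 * sin(2 * pi * f * (1:n) / fs)), tolerance = 1e-9)
  # full-wave rectification moves the spectral line to twice the frequency
  expect_equal(dominant_freq(sig$value, fs), 2 * f, tolerance = 1e-9)
  # invariant to adding constant offsets to both coordinates
  tr2 <- dplyr::mutate(tr, xc = xc + 11, yc = yc - 3)
  attributes(tr2) <- attributes(tr)[c("names", "row.names", "fs", "roi_label", "class")]
  expect_equal(l1_combine_time(tr2)$value, sig$value, tolerance = 1e-12)
})
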