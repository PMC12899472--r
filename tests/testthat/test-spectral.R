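test_that("default segmentation reproduces the documented bin spacings", {
  s600 <- welch_psd(rnorm(600), fs = 30)
  expect_equal(psd_resolution(s600), 0.4, tolerance = 1e-12)
  expect_equal(attr(s600, "segment_length"), 75L)
  expect_equal(attr(s600, "n_segments"), 15L)
  s660 <- welch_psd(rnorm(660), fs = 30)
  expect_equal(attr(s660, "segment_length"), 82L)
  expect_equal(round(psd_resolution(s660), 3), 0.366)
  expect_equal(diff(s600$freq_hz[1:2]), psd_resolution(s600), tolerance = 1e-12)
})

test_that("single-segment welch equals the brute-force DFT periodogram", {
  set.seed(21)
  for (n in c(64, 96)) {
    x <- rnorm(n)
    sp <- welch_psd(x, fs = 30, segment_length = n)
    expect_equal(sp$power, periodogram_bruteforce(x, 30), tolerance = 1e-9)
  }
})

test_that("sinusoid power localises at its frequency and integrates to A^2/2", {
  x <- sin(2 * pi * 5 * (0:599) / 30)
  sp <- welch_psd(x, fs = 30)
  expect_lte(abs(sp$freq_hz[which.max(sp$power)] - 5), psd_resolution(sp) / 2 + 1e-9)
  expect_equal(sum(sp$power) * psd_resolution(sp), 0.5, tolerance = 0.05 * 0.5)
  expect_true(all(welch_psd(rep(0, 600), fs = 30)$power == 0))
  expect_error(welch_psd(rnorm(10), fs = 30), class = "tremorcam_error_too_short")
})

test_that("bin-aligned band-interior sinusoids are recovered exactly", {
  for (f in c(2.4, 4.0, 6.0, 8.0, 10.0)) {
    x <- sin(2 * pi * f * (0:599) / 30)
    m <- peak_metrics(welch_psd(x, fs = 30), band = c(2, 12))
    expect_equal(m$ppf_hz, f, tolerance = 1e-9)
  }
  # non-aligned frequency: within one bin
  x <- sin(2 * pi * 5.1 * (0:599) / 30)
  m <- peak_metrics(welch_psd(x, fs = 30))
  expect_lte(abs(m$ppf_hz - 5.1), 0.4 + 1e-9)
})

test_that("L1 combination of spectra is an elementwise sum, commutative, associative", {
  set.seed(3)
  mk <- function(x) welch_psd(x, fs = 30)
  a <- mk(rnorm(300)); b <- mk(rnorm(300)); z <- mk(rep(0, 300))
  expect_equal(combine_psds_l1(list(a, a))$power, 2 * a$power)
  expect_equal(combine_psds_l1(list(a, z))$power, a$power)
  expect_equal(combine_psds_l1(list(a, b))$power, combine_psds_l1(list(b, a))$power)
  expect_equal(combine_psds_l1(list(combine_psds_l1(list(a, b)), z))$power,
               combine_psds_l1(list(a, combine_psds_l1(list(b, z))))$power,
               tolerance = 1e-12)
  # disjoint single peaks all survive with their heights
  tone <- function(f) mk(sin(2 * pi * f * (0:299) / 30))
  comb <- combine_psds_l1(list(tone(3), tone(5), tone(7)))
  for (f in c(3, 5, 7)) {
    i <- which.min(abs(comb$freq_hz - f))
    expect_equal(comb$power[i], sum(sapply(list(tone(3), tone(5), tone(7)),
                                           function(s) s$power[i])), tolerance = 1e-12)
  }
  expect_error(combine_psds_l1(list(a, mk(rnorm(200)))),
               class = "tremorcam_error_grid_mismatch")
})

test_that("band restriction keeps inclusive endpoints on the 0.4 Hz grid", {
  sp <- welch_psd(rnorm(600), fs = 30)
  b <- band_restrict(sp, c(2, 12))
  expect_equal(b$freq_hz[1], 2.0, tolerance = 1e-9)
  expect_equal(b$freq_hz[nrow(b)], 12.0, tolerance = 1e-9)
  expect_equal(nrow(b), 26L)
  full <- band_restrict(sp, c(sp$freq_hz[2], max(sp$freq_hz)))
  expect_equal(nrow(full), nrow(sp) - 1L)
  expect_error(band_restrict(sp, c(12.1, 12.2)), class = "tremorcam_error_empty_band")
})

test_that("peak metrics use 10*log10, break ties low, and error on zero power", {
  grid <- seq(0, 15, by = 0.4)
  mk <- function(p) structure(tibble::tibble(freq_hz = grid, power = p),
                              fs = 30, resolution = 0.4, n = length(grid),
                              segment_length = length(grid), n_segments = 1L,
                              label = "t",
                              class = c("power_spectrum", "tbl_df", "tbl", "data.frame"))
  p <- rep(0.001, length(grid)); p[grid == 5.2] <- 1
  m <- peak_metrics(mk(p))
  expect_equal(m$pp_db, 0); expect_equal(m$ppf_hz, 5.2)
  p2 <- p; p2[grid == 5.2] <- 100
  expect_equal(peak_metrics(mk(p2))$pp_db, 20)
  ptie <- rep(0.5, length(grid))
  expect_equal(peak_metrics(mk(ptie))$ppf_hz, 2.0)    # tie -> lowest in-band frequency
  expect_error(peak_metrics(mk(rep(0, length(grid)))),
               class = "tremorcam_error_undefined_peak")
  # pp_db is invariant to permuting off-peak bins, increasing in the peak bin
  p3 <- p; set.seed(1); off <- which(grid != 5.2)
  p3[off] <- sample(p3[off])
  expect_equal(peak_metrics(mk(p3))$pp_db, m$pp_db)
  p4 <- p; p4[grid == 5.2] <- 2
  expect_gt(peak_metrics(mk(p4))$pp_db, m$pp_db)
})

test_that("a full-pipeline 6 Hz blob lands within one bin of 6 Hz", {
  scene <- single_blob_scene(6, seed = 12)
  m <- video_metrics(scene$clip, single_blob_roi(), flicker = FALSE)
  expect_lte(abs(m$ppf_hz - 6), 30 / 74 + 1e-9)
})

test_that("flicker flags need edge-zone narrow peaks shared across RoIs", {
  clip <- three_roi_scene(flicker = list(freq_hz = 3, depth = 0.15), seed = 31)
  m <- video_metrics(clip, three_rois())
  expect_true(all(m$flicker_flagged))
  for (v in m$flicker_hz) expect_lte(min(abs(v - 3)), 30 / 74 + 1e-9)

  # genuine interior tremor in each RoI only: nothing flagged
  clean <- three_roi_scene(seed = 32)
  expect_false(any(video_metrics(clean, three_rois())$flicker_flagged))

  # all-zero spectra: no candidates, no flags
  z <- welch_psd(rep(0, 300), fs = 30, label = "a")
  expect_false(any(detect_flicker(list(z, z))$flagged))
  # single RoI: cross-RoI criterion unsatisfiable
  expect_warning(f1 <- detect_flicker(list(z)), "2 RoIs")
  expect_false(any(f1$flagged))
})

test_that("metrics are scale-free in intensity and monotone in amplitude", {
  base <- single_blob_scene(5.2, amp_px = 4, seed = 14, noise_sd = 0,
                            peak_intensity = 0.9)
  dim_scene <- single_blob_scene(5.2, amp_px = 4, seed = 14, noise_sd = 0,
                                 peak_intensity = 0.45)
  r <- single_blob_roi()
  m1 <- video_metrics(base$clip, r, flicker = FALSE)
  m2 <- video_metrics(dim_scene$clip, r, flicker = FALSE)
  expect_equal(m2$pp_db, m1$pp_db, tolerance = 1e-6)
  expect_equal(m2$ppf_hz, m1$ppf_hz)

  big <- single_blob_scene(5.2, amp_px = 8, seed = 14, noise_sd = 0,
                           peak_intensity = 0.9)
  m3 <- video_metrics(big$clip, r, flicker = FALSE)
  expect_gt(m3$pp_db, m1$pp_db)
  expect_equal(m3$ppf_hz, m1$ppf_hz)
})
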