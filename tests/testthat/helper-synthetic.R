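# Shared scene builders and independent oracles used across test files.

# One centred oscillating blob; RoI comfortably around it.
single_blob_scene <- function(freq_hz, amp_px = 4, seed = 1, noise_sd = 0.01,
                              frame_size = c(64, 64), duration_s = 20, fps = 30,
                              radius = 6, profile = "gaussian",
                              peak_intensity = 0.8, osc_axis = "horizontal") {
  c0 <- (frame_size - 1) / 2
  sc <- scene_spec(duration_s = duration_s, fps = fps, frame_size = frame_size,
                   blobs = list(blob_spec(center = c(c0[2], c0[1]), radius = radius,
                                          peak_intensity = peak_intensity,
                                          osc_freq_hz = freq_hz, osc_amp_px = amp_px,
                                          osc_axis = osc_axis, profile = profile)),
                   noise_sd = noise_sd, seed = seed)
  render_scene(sc)
}

single_blob_roi <- function(frame_size = c(64, 64), label = "right_hand") {
  half <- 20L
  x0 <- as.integer((frame_size[2] - 1) %/% 2 - half)
  y0 <- as.integer((frame_size[1] - 1) %/% 2 - half)
  roi(label, x0, y0, 2L * half + 1L, 2L * half + 1L)
}

# Three snug RoIs around three blobs at distinct interior frequencies,
# with a lit background so flicker banding has something to act on.
three_roi_scene <- function(flicker = NULL, seed = 1, freqs = c(5.2, 6.4, 7.6),
                            noise_sd = 0.01) {
  blobs <- list(
    blob_spec(c(16, 48), radius = 5, osc_freq_hz = freqs[1], osc_amp_px = 3),
    blob_spec(c(48, 48), radius = 5, osc_freq_hz = freqs[2], osc_amp_px = 3),
    blob_spec(c(80, 48), radius = 5, osc_freq_hz = freqs[3], osc_amp_px = 3))
  sc <- scene_spec(frame_size = c(96, 96), blobs = blobs, noise_sd = noise_sd,
                   background = 0.3, flicker = flicker, seed = seed)
  render_scene(sc)$clip
}

three_rois <- function() {
  dplyr::bind_rows(roi("left_hand", 2, 34, 28, 28),
                   roi("head", 34, 34, 28, 28),
                   roi("right_hand", 66, 34, 28, 28))
}

# --- independent oracles -------------------------------------------------

# Centre of mass by explicit double loop over pixels (0-based indices).
com_bruteforce <- function(values) {
  tot <- 0; sx <- 0; sy <- 0
  for (r in seq_len(nrow(values))) {
    for (cc in seq_len(ncol(values))) {
      v <- values[r, cc]
      tot <- tot + v
      sx <- sx + (cc - 1) * v
      sy <- sy + (r - 1) * v
    }
  }
  c(xc = sx / tot, yc = sy / tot)
}

# One-sided density-scaled periodogram via an explicit DFT double sum
# (independent of stats::fft), periodic Hamming window, mean removed.
periodogram_bruteforce <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / n)
  xx <- (x - mean(x)) * w
  nf <- n %/% 2 + 1
  p <- numeric(nf)
  for (k in 0:(nf - 1)) {
    re <- sum(xx * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xx * sin(-2 * pi * k * (0:(n - 1)) / n))
    p[k + 1] <- (re^2 + im^2) / (fs * sum(w^2))
  }
  last_unique <- if (n %% 2 == 0) nf - 1 else nf
  if (last_unique >= 2) p[2:last_unique] <- 2 * p[2:last_unique]
  p
}

# Dominant nonzero frequency of a series by plain DFT magnitude.
dominant_freq <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2 + 1)]
  mag[1] <- 0
  (which.max(mag) - 1) * fs / n
}

# Two-way ANOVA mean squares by explicit sum-of-squares loops.
anova_ms_bruteforce <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(y[i, ]) - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(y[, j]) - gm)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + gm)^2
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

icc_bruteforce <- function(y) {
  ms <- anova_ms_bruteforce(y)
  (ms$msr - ms$mse) / (ms$msr + (ncol(y) - 1) * ms$mse)
}
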