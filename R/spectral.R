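#' Welch power spectral density
#'
#' Averaged modified periodograms with a periodic Hamming window and 50%
#' overlap. The default segmentation sets the segment length to
#' `floor(N / segments)` with `segments = 8`; the transform length equals the
#' segment length (no zero padding), so the bin spacing is
#' `fs / floor(N / segments)` — for a 20-s recording at 30 Hz (600 samples)
#' that is 0.4 Hz, and for 22 s (660 samples) 0.366 Hz. Trailing samples that
#' do not fill a segment are dropped. Each segment is mean-removed before
#' windowing. Scaling is one-sided density (signal-units^2/Hz), so the
#' integral of the PSD over frequency estimates the signal variance.
#'
#' @param x A numeric signal, or a `motion_signal`/`motion_trace` column via
#'   a data frame with a `value` column and an `fs` attribute.
#' @param fs Sampling rate in Hz (taken from the attribute when `x` is a
#'   `motion_signal`).
#' @param segments Segmentation divisor: segment length is
#'   `floor(length(x) / segments)`. Default 8.
#' @param segment_length Explicit segment length in samples, overriding
#'   `segments` (e.g. `length(x)` gives a single-segment periodogram).
#' @param detrend Remove each segment's mean before windowing (default TRUE).
#' @param label Label stored on the result.
#' @return A `power_spectrum` tibble with columns `freq_hz`, `power` and
#'   attributes `fs`, `resolution` (Hz), `n`, `segment_length`, `n_segments`,
#'   `label`.
#' @export
welch_psd <- function(x, fs = NULL, segments = 8L, segment_length = NULL,
                      detrend = TRUE, label = NULL) {
  if (is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
    label <- label %||% attr(x, "roi_label")
    if (!"value" %in% names(x)) {
      abort_tc("Data-frame input to welch_psd() needs a `value` column.", "format")
    }
    x <- x$value
  }
  if (!is.numeric(x)) abort_tc("`x` must be a numeric signal.", "format")
  if (is.null(fs) || !is_scalar_number(fs) || fs <= 0) {
    abort_tc("A positive sampling rate `fs` is required.", "spec")
  }
  n <- length(x)
  if (n < 16L) {
    abort_tc(sprintf("Signal has %d samples; at least 16 are required.", n), "too_short")
  }
  L <- as.integer(segment_length %||% floor(n / segments))
  if (L < 4L || L > n) abort_tc("Segment length must be in [4, length(x)].", "spec")
  step <- max(1L, L %/% 2L)                       # 50% overlap
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / L)   # periodic Hamming
  u <- sum(w^2)                                   # window power normalisation
  nf <- L %/% 2L + 1L                             # one-sided bins incl. DC (+ Nyquist if L even)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    acc <- acc + (Mod(X[1:nf])^2) / (fs * u)
  }
  p <- acc / length(starts)
  # double the shared bins (all but DC and, for even L, Nyquist)
  last_unique <- if (L %% 2L == 0L) nf - 1L else nf
  if (last_unique >= 2L) p[2:last_unique] <- 2 * p[2:last_unique]
  out <- tibble::tibble(freq_hz = (0:(nf - 1L)) * fs / L, power = p)
  structure(out, fs = fs, resolution = fs / L, n = n, segment_length = L,
            n_segments = length(starts), label = label %||% NA_character_,
            class = c("power_spectrum", class(out)))
}

#' Frequency resolution of a spectrum
#' @param spectrum A `power_spectrum`.
#' @return Bin spacing in Hz.
#' @export
psd_resolution <- function(spectrum) attr(spectrum, "resolution")

#' Combine per-axis spectra by the L1 norm
#'
#' The spectra of the individual axes (x/y centroid coordinates, or the three
#' accelerometer axes) are collapsed into one by the L1 norm, which for
#' non-negative power values is the elementwise sum.
#'
#' @param spectra A list of `power_spectrum` objects on identical frequency
#'   grids.
#' @param label Label for the combined spectrum.
#' @return A `power_spectrum` with `power` equal to the elementwise sum.
#' @export
combine_psds_l1 <- function(spectra, label = "combined") {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  f0 <- spectra[[1]]$freq_hz
  for (s in spectra[-1]) {
    if (length(s$freq_hz) != length(f0) || max(abs(s$freq_hz - f0)) > 1e-9) {
      abort_tc("Spectra must share an identical frequency grid to be combined.",
               "grid_mismatch")
    }
  }
  p <- Reduce(`+`, lapply(spectra, function(s) s$power))
  out <- tibble::tibble(freq_hz = f0, power = p)
  structure(out, fs = attr(spectra[[1]], "fs"), resolution = attr(spectra[[1]], "resolution"),
            n = attr(spectra[[1]], "n"), segment_length = attr(spectra[[1]], "segment_length"),
            n_segments = attr(spectra[[1]], "n_segments"), label = label,
            class = class(spectra[[1]]))
}

#' Restrict a spectrum to an analysis band
#'
#' Keeps the bins with `lo <= f <= hi` (inclusive endpoints). The default
#' 2-12 Hz band discards slow drifting movements below 2 Hz and frequencies
#' above the hand-tremor range.
#'
#' @param spectrum A `power_spectrum`.
#' @param band `c(lo, hi)` in Hz.
#' @return The band-limited `power_spectrum` (attributes preserved).
#' @export
band_restrict <- function(spectrum, band = c(2, 12)) {
  check_band(band)
  tol <- psd_resolution(spectrum) * 1e-6
  keep <- spectrum$freq_hz >= band[1] - tol & spectrum$freq_hz <= band[2] + tol
  if (!any(keep)) {
    abort_tc(sprintf("No spectral bins fall inside the %.3g-%.3g Hz band.",
                     band[1], band[2]), "empty_band")
  }
  out <- spectrum[keep, ]
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       attributes(spectrum)[c("fs", "resolution", "n", "segment_length",
                                              "n_segments", "label")],
                       list(class = class(spectrum)))
  out
}

#' Peak tremor power and peak power frequency
#'
#' Peak power (PP) is the maximum of the PSD inside the analysis band,
#' expressed in dB as `10 * log10(max power)`; the peak power frequency (PPF)
#' is the frequency at which that maximum occurs — the dominant tremor
#' frequency. Ties resolve to the lowest frequency.
#'
#' @param spectrum A `power_spectrum` (full-range or already band-limited).
#' @param band `c(lo, hi)` analysis band in Hz (default 2-12).
#' @param exclude_hz Optional frequencies (Hz) whose bins (within half a bin)
#'   are excluded before taking the maximum — the opt-in path for discarding
#'   flicker-flagged bins.
#' @param label Label override for the output row.
#' @return A one-row tibble: `label`, `pp_db`, `ppf_hz`, `band_lo`, `band_hi`.
#' @export
peak_metrics <- function(spectrum, band = c(2, 12), exclude_hz = numeric(), label = NULL) {
  sp <- band_restrict(spectrum, band)
  if (length(exclude_hz)) {
    half <- psd_resolution(sp) / 2 + 1e-12
    drop <- vapply(sp$freq_hz, function(f) any(abs(f - exclude_hz) <= half), logical(1))
    sp <- sp[!drop, ]
  }
  if (nrow(sp) == 0L || max(sp$power) <= 0) {
    abort_tc("All in-band power is zero (or excluded); peak power is undefined.",
             "undefined_peak")
  }
  i <- which.max(sp$power)                         # first maximum = lowest frequency on ties
  tibble::tibble(label = label %||% attr(spectrum, "label"),
                 pp_db = 10 * log10(sp$power[i]),
                 ppf_hz = sp$freq_hz[i],
                 band_lo = band[1], band_hi = band[2])
}

#' Flag narrow lighting-flicker peaks shared across RoIs
#'
#' Fluorescent lighting combined with a CMOS rolling shutter injects narrow
#' false peaks near the edges of the analysis band, simultaneously in every
#' RoI of a clip. A candidate peak is flagged when (a) it is a local maximum
#' inside the edge zones `[lo, lo + edge_width]` or `[hi - edge_width, hi]`,
#' (b) its -3 dB width spans at most `max_width_bins` bins, and (c) every
#' other RoI spectrum of the clip has such a candidate within one bin of the
#' same frequency. Flagged peaks are recorded, not removed; pass them to
#' [peak_metrics()] via `exclude_hz` to recompute metrics without them.
#'
#' @param spectra A list of `power_spectrum` objects, one per RoI of the same
#'   clip (at least 2; with a single spectrum the cross-RoI criterion is
#'   unsatisfiable and everything is unflagged, with a warning).
#' @param band `c(lo, hi)` analysis band in Hz.
#' @param edge_width Width of each edge zone in Hz (default 2).
#' @param max_width_bins Maximum -3 dB width in bins (default 3: a pure
#'   spectral line falling between two bins splits its energy and its
#'   half-power width can reach three bins under Hamming leakage; anything
#'   wider is a genuine broadband feature).
#' @return A tibble with one row per spectrum: `label`, `flagged`, and
#'   `flicker_hz` (list-column of flagged frequencies); attribute
#'   `clip_flagged` is `TRUE` if any RoI was flagged.
#' @export
detect_flicker <- function(spectra, band = c(2, 12), edge_width = 2, max_width_bins = 3L) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  labels <- vapply(seq_along(spectra), function(i) {
    attr(spectra[[i]], "label") %||% paste0("roi_", i)
  }, character(1))
  if (length(spectra) < 2L) {
    rlang::warn("detect_flicker() needs spectra from >= 2 RoIs; returning no flags.")
    out <- tibble::tibble(label = labels, flagged = FALSE,
                          flicker_hz = list(numeric()))
    return(structure(out, clip_flagged = FALSE))
  }
  cands <- lapply(spectra, flicker_candidates, band = band,
                  edge_width = edge_width, max_width_bins = max_width_bins)
  res <- vapply(spectra, psd_resolution, numeric(1))
  flags <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    keep <- vapply(cands[[i]], function(f) {
      all(vapply(seq_along(spectra)[-i], function(j) {
        tol <- max(res[i], res[j]) + 1e-9
        length(cands[[j]]) > 0 && any(abs(cands[[j]] - f) <= tol)
      }, logical(1)))
    }, logical(1))
    flags[[i]] <- cands[[i]][keep]
  }
  out <- tibble::tibble(label = labels,
                        flagged = lengths(flags) > 0L,
                        flicker_hz = flags)
  structure(out, clip_flagged = any(out$flagged))
}

# Narrow local maxima within the band-edge zones of one spectrum.
flicker_candidates <- function(spectrum, band, edge_width, max_width_bins) {
  sp <- band_restrict(spectrum, band)
  p <- sp$power; f <- sp$freq_hz; nb <- length(p)
  if (nb < 3L || max(p) <= 0) return(numeric())
  in_edge <- (f <= band[1] + edge_width + 1e-9) | (f >= band[2] - edge_width - 1e-9)
  out <- numeric()
  for (i in seq_len(nb)) {
    if (!in_edge[i] || p[i] <= 0) next
    left <- if (i > 1L) p[i - 1L] else -Inf
    right <- if (i < nb) p[i + 1L] else -Inf
    if (!(p[i] > left && p[i] >= right)) next
    half <- p[i] / 2                               # -3 dB level
    wbins <- 1L
    j <- i - 1L
    while (j >= 1L && p[j] >= half) { wbins <- wbins + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= nb && p[j] >= half) { wbins <- wbins + 1L; j <- j + 1L }
    if (wbins <= max_width_bins) out <- c(out, f[i])
  }
  out
}
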