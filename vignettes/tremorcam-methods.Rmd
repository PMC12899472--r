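---
title: "Centre-of-mass video tremor quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centre-of-mass video tremor quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorcam)
```

## The measurement problem

Pathological tremor — essential tremor at roughly 4–12 Hz, dystonic tremor at
3–7 Hz — is conventionally quantified with body-worn accelerometers. A
contactless alternative is to extract the oscillation from ordinary 2D video
of the seated patient. `tremorcam` implements a deliberately simple video
descriptor: the motion of the *intensity-weighted centre of mass* (CoM) of a
fixed rectangular region of interest (RoI) drawn once around each tracked
body part (left hand, right hand, head), followed by Welch spectral analysis
of the CoM trajectory. The package also implements the accelerometer
reference pipeline and the agreement statistics used to compare the two
modalities, plus a synthetic-scene generator that supplies ground truth for
every stage.

## The video model

For consecutive grayscale frames $F_t$, $F_{t+1}$ restricted to an RoI, the
difference image is

$$D_t = \lvert F_{t+1} - F_t \rvert,$$

min–max normalised per difference frame to $[0,1]$. Only changed (moving)
pixels carry intensity, so the static background vanishes. Treating the
normalised intensities $I(x, y)$ as masses, the centroid is

$$x_c = \frac{\sum x\, I(x,y)}{\sum I(x,y)}, \qquad
  y_c = \frac{\sum y\, I(x,y)}{\sum I(x,y)},$$

with 0-based pixel coordinates, giving one $(x_c, y_c)$ sample per frame
pair — a motion time series at the frame rate (30 Hz in the intended
recording setup, so 2 Hz–12 Hz tremor lies below Nyquist).

Decisions worth making explicit:

* **Absolute differences.** Normalising "to a range of 0 to 1" and using
  intensities as masses both require non-negative values; signed differences
  would make the centroid ill-defined.
* **Normalisation scope.** Per-difference-frame min–max is the default; it
  makes the centroid exactly invariant to global intensity scaling (a dimmer
  copy of a clip yields the identical trace). A per-clip global
  normalisation is available (`norm = "global"`). With per-frame
  normalisation and additive noise, a frame pair in which the target is
  momentarily still is rescaled noise; its centroid then sits near the RoI
  centre. For snug RoIs centred on the body part this point coincides with
  the mean target position and only mildly distorts the waveform; for large,
  badly off-centre RoIs it injects spurious harmonics — one reason the
  recording protocol draws RoIs snugly around the tracked part.
* **Degenerate pairs.** An all-constant difference (max = min) would divide
  by zero; such pairs carry the previous centroid forward (the RoI geometric
  centre if there has been no motion yet). A fully static scene therefore
  produces a constant trace, not NaNs.
* **Coordinate origin.** 0-based, top-left, half-open rectangles
  $[x, x+w) \times [y, y+h)$, chosen for composability with array slicing.
  Any fixed offset convention cancels in the mean-centred spectra.

## Spectral analysis

Each coordinate series is mean-removed and transformed with Welch's method:
periodic Hamming window, 50% overlap, segment length $\lfloor N/8 \rfloor$
samples, transform length equal to the segment length (no zero padding),
one-sided density scaling. The segment-length policy is the part that fixes
the frequency grid: a 20-s clip at 30 fps gives $N \approx 600$, segments of
75 samples and a bin spacing of $30/75 = 0.4$ Hz; a 22-s clip gives 660
samples, segments of 82 and $30/82 \approx 0.366$ Hz. With 50% overlap this
averages 15 segments; trailing samples that do not fill a segment are
dropped. The common "8 segments with 50% overlap" rule
($L \approx N/4.5$) would give roughly 0.22 Hz bins instead and is
deliberately not used.

The two coordinate spectra are collapsed by the **L1 norm** — for
non-negative power values, an elementwise sum. An alternative reading of the
pipeline combines the coordinates in the *time* domain
(`combine = "time"`: $|x_c - \bar x_c| + |y_c - \bar y_c|$, then one PSD).
The two are mathematically different: full-wave rectification moves a pure
oscillation's energy to twice its frequency. Both paths are implemented; the
PSD-domain combination is the default because the tremor metrics are defined
on the combined PSD, and because it preserves the physical frequency. The
ambiguity is preserved behind the switch rather than resolved.

The combined spectrum is restricted to the **2–12 Hz band** (inclusive
endpoints): below 2 Hz lie slow drifting movements, above 12 Hz nothing
tremor-related at these frame rates. The metrics are

* **PP (peak power)** — $10\log_{10}$ of the maximum in-band PSD value, in
  dB. $10\log_{10}$ is the convention for a power quantity; the absolute dB
  scale is relative (uncalibrated video units), so PP supports
  within-protocol comparisons, not absolute amplitude.
* **PPF (peak power frequency)** — the frequency of that maximum; ties
  resolve to the lowest frequency (deterministic and conservative).

The accelerometer side runs the same machinery per axis (after mean removal,
which discards gravity and DC), sums the three axis spectra, and extracts
the same metrics. At the nominal 100 Hz and ~20 s, $\lfloor 2000/8\rfloor =
250$ gives 0.4 Hz bins, coincidentally matching the video side. No
resampling and no time synchronisation are performed: both modalities are
reduced to scalar frequency-domain metrics, which are insensitive to time
shifts under steady-state tremor.

## Flicker artifacts

Fluorescent lighting recorded through a CMOS rolling shutter injects narrow
false peaks near the band edges (2–4 Hz and 10–12 Hz), simultaneously in
every RoI. `detect_flicker()` flags a peak when it (a) is a local maximum in
an edge zone, (b) is narrow, and (c) coincides within one bin with a peak in
*all* other RoI spectra of the clip. Narrowness is defined as a −3 dB width
of at most **3 bins**: a pure line falling midway between two bins splits
its energy across both, and with Hamming leakage its half-power width can
genuinely reach three bins; a 2-bin rule silently misses exactly the
off-grid lines the detector exists for, while anything wider than 3 bins is
a broadband feature. Flagged peaks are recorded, never removed; excluding
them from the peak search is opt-in (`exclude_flagged = TRUE`), since the
recordings that motivated the rule were inspected rather than automatically
cleaned.

## Agreement statistics

Video and IMU are treated as two raters of each subject. Concordance uses
the **two-way random effects, single measures, consistency ICC**, computed
from explicit ANOVA mean squares with $k = 2$:

$$\rho = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E},$$

with the Fleiss–Shrout F-based 95% confidence interval
($F_L = F / F_{1-\alpha/2}(n-1,(n-1)(k-1))$,
$F_U = F \cdot F_{1-\alpha/2}((n-1)(k-1), n-1)$, bounds
$(F_\cdot - 1)/(F_\cdot + k - 1)$). Consistency ICC is invariant to a
constant offset between modalities — appropriate here, where video power is
on an arbitrary scale. Reliability classes use 0.50/0.75/0.90 thresholds
with boundaries mapping upward (0.75 is "good"). The mean-squares estimator
is biased low at small $n$ (about $-0.06$ at $n = 6$ for $\rho = 0.8$ in our
simulations) and consistent as $n$ grows; the confidence interval's coverage
is close to nominal at $n = 30$.

**MAE** is $\mathrm{mean}\,|v_i - w_i|$. The relative MAE normalisation is
not uniquely determined by the report format it mirrors; the default is
per-subject, $100 \cdot \mathrm{mean}(|v_i - w_i| / |w_i|)$ (zero-reference
subjects excluded with a warning) — it naturally exceeds 100% when
individual references are small, as dB-scale peak powers can be; the
cohort-mean form $100 \cdot \mathrm{MAE}/|\bar w|$ is available via
`relative = "cohort_mean"`. **Bland–Altman** limits use
$\bar d \pm 1.96\,\mathrm{SD}(d)$ with the sample SD; at $n = 30$ the
difference from a t-quantile is negligible.

## The synthetic generator

`render_scene()` draws Gaussian (or antialiased disc) blobs whose centres
move as $c + a\sin(2\pi f t / \mathrm{fps})$, evaluated at real-valued
offsets so sub-pixel motion produces a clean spectral line; additive
Gaussian pixel noise is applied before clipping to $[0,1]$ (the clip is a
mild nonlinearity at extreme settings). Amplitudes below half a pixel are
rejected as outside the supported regime. `render_imu()` produces the
matched reference: acceleration $-(2\pi f)^2 a \sin(2\pi f t)$ distributed
over three axes by a unit mixing vector, plus white noise and a gravity
offset. `make_cohort()` ties both to one ground truth per subject and
writes videos, IMU CSVs, RoIs and a manifest.

Flicker is generated as *row-phased banding*,
$1 + d\sin(\pi f t/\mathrm{fps} + 2\pi y / \lambda)$: horizontal bands that
drift vertically, the visual signature of rolling-shutter flicker. A
spatially uniform modulation cannot be used — the centroid of a positively
scaled image does not move, so uniform flicker produces no spectral artifact
at all. Because frame differencing rectifies the banding, the temporal phase
rate is set to $f/2$ so that the drifting difference pattern — and hence the
centroid artifact line — appears at exactly `freq_hz`; that parameter names
the frequency of the injected artifact. The default banding wavelength
$\lambda$ is one frame height (one band visible per frame): a snug RoI then
sees about a quarter band, which maximises centroid drift; much longer
wavelengths are near-uniform within an RoI and, consistent with the argument
above, produce no measurable artifact.

Default study conditions: 30 fps, 20 s clips, 2–12 Hz oscillations, 100 Hz
IMU sampling, cohort frequencies uniform on 3–9 Hz, amplitudes 2–6 px,
pixel noise SD 0.01, IMU noise SD 0.1 m/s², flicker depth around 0.15 when
injected. Frame geometry in examples and tests is small (48–96 px frames)
because geometry only positions pixels and does not change the signal
structure; the original recording geometry (1280×720) differs only in cost.
A pixel-to-metre factor of 0.001 links blob amplitude to IMU displacement
(roughly 1 mm per pixel at a ~2 m camera distance).

What the generator does *not* emulate — and what passing tests therefore do
not establish about clinical data: hand/face appearance and contrast
structure, voluntary and postural movement superimposed on tremor,
rotational (yaw/pitch/roll) head kinematics that a 2D centroid cannot
resolve, camera shake, compression artifacts, and complex backgrounds.
Head-tremor agreement in particular is limited by physics, not software:
accelerometers near the rotation axis and in-plane centroids both capture
rotational tremor only indirectly.

## Numerical and container choices

* Video I/O uses lossless multi-page TIFF (32-bit float) with a JSON
  sidecar for the frame rate; cohort videos are written at 8-bit, matching
  consumer-video bit depth. Any stack readable by the TIFF reader works;
  frame rate can always be overridden (`fps =`).
* Welch on fewer than 16 samples, bands outside Nyquist, empty band
  restrictions, all-zero in-band spectra, out-of-bounds RoIs and degenerate
  ICC inputs all raise classed errors (`tremorcam_error_*`) rather than
  propagating NaN.
* All generators are seeded and bit-reproducible; pipeline outputs are
  deterministic functions of their inputs, so re-running a saved
  configuration reproduces results exactly.

## Problem sizes used in the shipped checks

The package's own validation uses: the documented 600- and 660-sample
resolution cases; 1000 random images for the centroid oracle; 9 grid
frequencies × 5 seeds through both full pipelines; 200 random paired sets
for the ICC oracle plus 1000 simulated 30-subject cohorts for CI coverage;
100 flicker and 100 clean three-RoI scenes; and one end-to-end 30-subject
cohort in which cross-modality PPF ICC exceeds 0.95. These sizes are the
package's choice of a thorough desk-scale battery.

## Known limitations

Uncalibrated power (no physical amplitude), manual RoI placement, no RoI
tracking, no multitaper or parametric spectra, no harmonic analysis, no
prominence-based peak picking (the peak is the plain in-band maximum), no
coherence between RoIs, and metrics-level (not sample-level) modality
comparison. These mirror the boundaries of the validated method rather than
accidental gaps.
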