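---
title: "The photon-pixel coupling pipeline: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The photon-pixel coupling pipeline: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonpixel)
```

## The measurement principle

Photon-pixel coupling acquires many electrical channels in parallel by
optical multiplexing. Each skin-contact sensor amplifies its local
electrodermal current through a high-gain transistor cascade and drives
one white LED of a 20 × 10 matrix. A fixed camera inside a dark,
sealed enclosure images the matrix through a semi-translucent diffuser
at discrete intervals. Every LED's luminance is then read back from the
image as a *single pixel value* at a calibrated coordinate, and that
8-bit value is mapped linearly to a percentage: pure black is 0 %, pure
white 100 %. A video camera is, in effect, a massively parallel
analog-to-digital converter: 200 channels are digitised per frame, and
the sampling rate is bounded only by the frame rate.

This package implements that chain as software, together with a forward
model of the physical rig. Because no public recordings of the original
apparatus exist, the simulator is the package's data source: it renders
frames from known per-channel signals, so every downstream stage
(spot-centre detection, decoding, gain calibration, heatmap
classification) can be validated against ground truth.

## The forward model

`simulate_session()` composes three stages, each with explicit
parameters.

**Sensor response.** Each channel has a fixed multiplicative gain drawn
once per `sensor_population()` (log-normal, `gain_sdlog = 0.1` by
default, i.e. roughly a 10 % manufacturing spread) and a common
`saturation_level` (default 1 signal unit). Brightness is
`min(1, gain * signal / saturation)`, with a hard clamp to 1 whenever
the signal reaches the saturation level. The true luminance-vs-current
curve of the LEDs is not documented for the original rig; a monotone
saturating response is the standard assumption and is recorded as such.
All calibration claims in this package are restricted to the linear
(unsaturated) part of this response.

**Optics.** `led_grid()` lays the LEDs on a regular lattice with a
one-pitch margin (at the default 320 × 240 px frame: 15.2 px column
pitch, 21.8 px row pitch) and adds a per-LED geometric jitter
(`jitter_sd = 1` px, truncated at 3 sd), drawn once at construction —
the physical LEDs are soldered slightly off their ideal positions but do
not move between sessions. A spot is an isotropic Gaussian with
sd `psf_sigma` (1.5 px), and the diffuser sheet adds an independent blur
`diffuser_sigma` (1 px); the two convolve to a total spot sd of
`sqrt(psf_sigma^2 + diffuser_sigma^2)` ≈ 1.8 px. Overlapping spots add,
the background sits at `background_level` (8 of 255), and white LEDs
make the three RGB channels identical before noise.

**Camera.** Additive Gaussian pixel noise (`noise_sd`, a fraction of
full scale, default 1 % for the population and 0.5 % in the pipeline
demo), clipped to [0, 255] and quantised to 8 bits. Frames are stored
as lossless PNG by default; a JPEG mode exists to emulate the original
storage format's compression artifacts but is off everywhere precision
is asserted, so that tests measure the method and not the codec.

**Signal dynamics.** Synthetic subjects follow a per-channel baseline
(uniform on 0.35–0.65 signal units) plus a slow Gaussian random walk
(`drift_sd = 0.002` per frame) and optional step perturbations at 15 and
30 minutes, standing in for the two glucose doses of the original
protocol as signal events only — there is no metabolic model. A
`common_signal` mode feeds every channel the same signal, which is the
wiring used for gain-calibration sessions.

A 60-minute session at the 5-second interval yields exactly
`floor(3600 / 5) = 720` frames; session timing is fully parametric
(the capture limits enforced by `pipeline_config()` are 3–60 s intervals
and 3–120 min durations).

## The vector map

Decoding samples *one pixel per LED*, so the pixel coordinates of all
200 LED centres must be known. The original procedure selected the
brightest pixel of each LED by hand; `detect_led_centers()` automates
this on an all-LEDs-on calibration frame: grayscale conversion, Gaussian
smoothing (sd of about half the spot sd), 3 × 3 local maxima above an
adaptive floor, then greedy non-maximum suppression at the
`min_separation` radius (ties broken towards smaller y, then smaller x),
and finally a refinement to the argmax pixel of the raw image near each
peak. Weak surplus maxima — below half the median peak height above
background — are pruned to the expected count; surplus peaks of
comparable height raise an ambiguity error rather than silently guessing,
and a deficit raises a detection-failure error naming the shortfall.

Detected centres are ordered row-major from the top-left of the image
(rows are clustered by gaps in the sorted y coordinates, which tolerates
jitter up to roughly half a row pitch), making the ordering invariant to
detection order. On simulated all-on frames with 1 px jitter the
detector recovers 200/200 centres within 1.5 px (typically under
0.7 px). Manually curated maps are supported through the same CSV
format (`led_index,label,x,y`, 0-based integer pixels) and a JSON
variant that embeds the image dimensions.

**Labels.** Sensors are named `"line.sensor"` — `"2.5"` is sensor 5 on
vertical sensor line 2. The physical vest has 8 lines of 11–13 sensors
per body side while each matrix half has 10 columns of 10 LEDs, and the
original convention explicitly allows any sensor-to-LED assignment as
long as it is recorded. The default `layout_spec()` therefore uses the
simplest recorded bijection: line = matrix column (1–20), sensor = row
from the top (1–10), so label `"1.1"` is LED 1 and every label is unique
across the whole matrix; the left half maps to the dorsal side (the
matrix-organisation text and the figure caption of the source apparatus
disagree on this assignment, so it is configurable). Any other layout —
including per-side line numbering or 13-sensor lines wrapped across
columns — can be supplied as an explicit `label_table`.

## Decoding

`pixel_to_percent()` reduces the 24-bit pixel to one scalar by the
arithmetic mean of R, G and B — white LEDs make the channels nominally
equal, and no reduction formula is documented for the original software,
so the mean is the recorded assumption (max-channel and BT.601 luma are
available behind a switch). The percent mapping is linear,
`100 · gray / 255`, with no gamma. The default decode reads exactly the
one mapped pixel; a 3 × 3-mean robust mode exists for noisy data but is
off wherever behaviour is asserted.

With zero noise and jitter the decoded percentage at a channel is a
monotone function of the channel's true brightness (rank correlation 1.0
over a 10-level ladder). It is *not* proportional to it across
channels: the pixel under an LED's integer coordinate sits at a
channel-specific sub-pixel offset from the true centre, which acts as a
small extra per-channel gain. That is exactly the kind of fixed
multiplicative disparity the gain calibration removes.

## Gain calibration

Two matrices, one identity. In a test session all electrodes are wired
to a single skin point, so every sensor amplifies the same signal; the
decoded session mean is `M_test` (the per-cell mean over the session's
frames — one stored value per sensor, with frame noise averaged out).
The offset matrix is

    G_test[i,j] = MAX(M_test) - M_test[i,j]

and during experiments each decoded matrix is corrected additively:

    N[i,j] = M_real[i,j] + G_test[i,j].

Both are also provided in row-vector form over LEDs 1–200
(`compute_gain_vector()` / `apply_gain_vector()`), numerically identical
to the matrix form after row-major flattening. Properties that follow
directly and are enforced by tests: `min(G) = 0`; self-calibration
`apply_gain(M_test, compute_gain(M_test))` is constant at `max(M_test)`;
a zero gain matrix is the identity.

Two deliberate limitations are kept rather than "fixed". First, the
correction is *additive*, as specified, although the simulated gain
disparity is multiplicative: the offsets cancel the disparity exactly
only at the common-signal strength at which they were measured. The
package asserts calibration quality under that matched condition (where
cross-channel dispersion under a shared signal shrinks by well over 5×,
noise-limited), and asserts only rank-stability of the offsets across
strengths. Second, calibrated values can exceed 100 %; since
percentages cannot exceed full white they are clipped at 100 and the
clipped-cell count is attached as an attribute (`n_clipped`) and
surfaced in the pipeline report — the original method does not say how
(or whether) such overflow was handled.

## Heatmaps and classification

`average_encoded_matrix()` reduces a calibrated series to one matrix per
subject: the element-wise mean of the first `window` matrices (a CLI
flag allows an offset), rescaled to [0, 1]. At the default window of 20
matrices a 200-channel rig averages 4000 scalar measurements — 100 s of
signal at the 5-s interval.

For transport as an image, the heatmap is rendered as 10 × 20 coloured
rectangles under an invertible three-anchor colormap and decoded back by
projecting each cell's colour onto the colormap curve (a dense LUT
nearest-neighbour search, with an off-curve tolerance that rejects
foreign colours). The default anchors are pure blue → white → red.
Half-intensity ("dark") anchors were considered to match the visual
convention of the original heatmaps but are rejected by the constructor:
after 8-bit quantisation the two half-curves collapse onto the same
grays near the white midpoint, and the measured round-trip error
(0.0049) breaks the 1/255-per-cell bound that the pure anchors meet with
margin (0.0012). Any anchor set that passes the constructor's
invertibility self-test may be used and is stored alongside encoded
images.

The classifier is a single-hidden-layer feed-forward network (sigmoid
output, binary cross-entropy, via `nnet`), mapping the 200 flattened
cells to a trust value in [0, 1]; below 0.5 reads healthy, above 0.5
predisposed to type 2 diabetes, and exactly 0.5 is reported as
indeterminate rather than assigned to a class. The hidden layer
defaults to 8 units: with 200 inputs and cohorts of a few dozen to a few
hundred heatmaps, larger layers (e.g. 32 units, 6465 weights) only add
fitting cost without improving held-out accuracy on the synthetic
benchmark, where 8 units already reach 1.0. A logistic-regression
fallback (`method = "logistic"`) covers the smallest cohorts. Training
is deterministic under a fixed seed and supports the three cohort
regimes (all, female-only, male-only) via each heatmap's `group` field.

`synthetic_cohort()` generates the evaluation data: by default the
study's arm sizes (5 healthy female, 8 diabetic female, 13 healthy male,
10 diabetic male = 36 heatmaps), each subject being a baseline plus a
smooth class-contrast pattern scaled by `separation` plus per-cell
noise. With `separation = 0.2` the classes are cleanly separable
(held-out accuracy ≥ 0.9 is required by the tests); with
`separation = 0` the cohort carries no class information and held-out
accuracy must stay within binomial noise of 0.5. These synthetic
cohorts establish that the *pipeline* — encoding, averaging, colormap
transport, training, thresholding — preserves class structure; they say
nothing about real diagnostic performance, for which the original
clinical data would be needed.

## Numerical and scale choices

- Coordinates are 0-based, x = column, y = row, pixel centres at
  integers; R's 1-based array indexing is confined to the rendering and
  sampling internals.
- Frames are 8-bit; all precision claims are made against that
  quantisation (e.g. the 1/255 colormap bound).
- Determinism: every stochastic component (gain draw, jitter draw,
  session noise, cohort generation, weight initialisation) takes a seed,
  and seeded runs restore the caller's RNG state. Identical
  configuration and seed give byte-identical frames.
- The test suite exercises full-scale rigs (200 LEDs, 320 × 240 px)
  where the property concerns that scale — centre recovery, dispersion
  shrinkage — and 6–10-LED rigs elsewhere; a full 720-frame subject
  session is run by `scripts/acceptance.R` (about half a minute) rather
  than in every test.

## Known limitations

- No circuit-level electronics, no physiology: signal dynamics are a
  stochastic stand-in for electrodermal activity, and the glucose doses
  are plain step perturbations.
- The additive gain correction inherits the printed method's
  strength-dependence under multiplicative gain disparity (above).
- Row clustering in centre detection assumes jitter well below the row
  pitch; pathological layouts should supply a manual map file.
- The classifier benchmark is synthetic and separable by construction;
  no clinical claim is made or testable here.
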