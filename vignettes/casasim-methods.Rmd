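---
title: "Simulating semen microscopy videos and benchmarking CASA algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating semen microscopy videos and benchmarking CASA algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(casasim)
library(dplyr)
```

## Why simulate semen images

Computer-assisted semen analysis (CASA) systems segment, localize and track
sperm cells in bright-field microscopy video.  Validating those algorithms
on real specimens is hard because the ground truth — where every cell really
is, and which track belongs to which cell — is unknown and must be labeled
by hand.  `casasim` generates life-like 2-D grayscale semen videos in which
the exact position and swim mode of every cell in every frame are known by
construction, then scores detection and tracking algorithms against that
truth.  The package contains both sides of the benchmark: the generative
model (cell appearance + four swim modes + scene composition) and the
evaluation stack (five detectors, four multi-target trackers, OSPA,
precision/recall, and CLEAR-MOT scoring).

## The cell appearance model

A cell image is synthesized from point sources through three point-spread
functions on a uniform background `B_L` (default 204, 80% of white):

* **Head centre** — the rasterized head point is convolved with an
  anisotropic Gaussian (`make_gaussian_psf()`, default
  $\sigma_x = 1.86$, $\sigma_y = 2.86$ px, $25 \times 25$ support), scaled
  so the peak is exactly `head_peak` (255), complemented, and composited
  onto the background: `I5 = max(0, (255 - I3) - (255 - B_L))`.  An
  isolated default head therefore has a darkest pixel of exactly 0 and the
  far field equals `B_L` exactly.
* **Membrane halo** — the same head point convolved with the
  positive-clipped Laplacian of an anisotropic Gaussian
  (`make_halo_psf()`, $\sigma = (2.79, 4.29)$ px), scaled to peak at
  `membrane_peak` (51).  Clipping keeps the bright outer lobe that renders
  the characteristic horseshoe halo.
* **Flagellum** — the tail polyline (200 points) convolved with a clipped
  isotropic Laplacian-of-Gaussian ridge kernel (`make_ridge_psf()`,
  $\sigma_f = 1.5$ px), scaled to peak at `flagellum_peak` (13, ~5% of
  white).  The clipping is deliberate: the unclipped LoG response of a line
  is a double ridge with a dark core, whereas an observed flagellum is a
  single faint bright line.

The final image is `I9 = clip(I5 + I6 + I8, 0, 255)`, quantized to 8 bits.
Intermediate buffers stay real-valued and unclipped except where the
head-centre compositing explicitly applies `max(0, .)`.

**Calibration gains.** The head and membrane gains are fixed constants
computed once from a single-point kernel response
(`calibrate_gain()`), so overlapping cells superpose additively instead of
renormalizing the frame.  The flagellum gain cannot come from a single
point: a dense polyline superposes hundreds of point responses, so its
ridge would overshoot the printed peak.  `render_flagellum()` therefore
calibrates against the rendered line response itself, and the scene
simulator freezes each cell's flagellum gain as a per-cell calibration
constant at (re)initialization.  Hyperactive cells recalibrate only while
their trailing-tail history is still filling, because the polyline length
is genuinely changing there.

Conventions chosen where the imaging model is silent: the origin is the
centre of the top-left pixel with x rightward and y downward (0-based);
continuous positions round half-up when rasterized; convolution uses zero
padding cropped to the frame, so cells fade naturally at the borders.

## The four swim modes

```{r modes, eval = FALSE}
sc <- simulate_semen(tracking_config(20, duration = 2), seed = 1)
plot_frame(sc, 0)
```

* **Circular** (`circular_head()`, `circular_tail()`): a sinusoid-modulated
  circular path, radius `r_c`, beat amplitude `a` at frequency `f_s` (Hz),
  circular rate configured in degrees/s (`omega_deg`; 50 deg/s corresponds
  to 50/360 cycles/s — the degree convention makes the benchmark parameter
  table usable verbatim).  The tail is a travelling sine wave of wavelength
  `lambda` whose local amplitude grows linearly along the flagellum,
  `b(k) = a(\alpha \lambda k / M + \beta)` with `alpha = 0.02`,
  `beta = 0.8`.  The printed tail rotation by the beat phase would spin the
  tail at 4 Hz; since the tail should trail the direction of movement, the
  tail is instead rotated by the instantaneous analytic heading of the
  head path (a documented interpretation of an ambiguous source formula).
* **Linear mean** (`linear_head()`, `linear_tail()`): straight-line
  progression at `V` px/s in direction `theta_r`, plus a rotated
  "ribbon" oscillation: along-track sinusoid of amplitude `r_v/2` at
  `2 f_l`, across-track sum of a fundamental and third harmonic (ratio
  `A_har`) normalized by `ribbon_constant()` so the across-track amplitude
  is exactly `r_h/2`.  The tail oscillations are shaped by a transformed
  sigmoid `b1`, a decaying exponential `b2`, and corrected by `b3`
  (`linear_amplitude_profiles()`), with `alpha = 22`, `beta = -2`,
  `gamma1 = 5`, `gamma2 = 1.5`; the profile index is read as the tail
  index `k`.  The tail index grid is `seq(0, M, length.out = M)`, so the
  printed endpoint identities hold at both `k = 0` and `k = M` while the
  polyline still has exactly `M` points.
* **Hyperactive** (`hyperactive_step()`, `trailing_tail()`): zero-drift
  Brownian motion with per-axis increments `N(0, sigma_b^2 T)` per frame
  (exact discretization; independent axes).  The tail is the head's own
  trajectory: a piecewise-linear curve through the last
  `n = ceil(0.2 s / T)` positions, arc-length-resampled to `M` points.
* **Immotile** (frozen): head and tail fixed for the whole video; the tail
  is a snapshot of a hyperactive-style trailing tail.

Cells are placed uniformly at random with uniform headings; each
oscillatory mode also gets a uniform random beat-phase offset so cells in a
scene do not beat in lockstep.  These randomizations are not in the source
description of the models (which describes single cells) but are the
obvious scene-level ergodicity choice.

Three scene features extend the basic models: per-frame positional jitter
(`jitter_sigma`; the jittered position is what is rendered *and* recorded
as truth, since that is what a detector could at best recover), per-cell
intensity factors in (0, 1] that scale the cell's whole deviation from
background (emulating depth in the counting chamber), and a 4x4 Markov
swim-mode transition matrix evaluated once per second
(`transition_model()`); on a transition the cell re-initializes in the new
mode at its current position and heading.

## Scene composition, noise, and artifacts

`simulate_semen()` renders `round(duration * fps)` frames (default 15 FPS).
Heads and halos are stamped as calibrated kernels (a head is a single
point, so its convolution is just the kernel centred at the rounded pixel);
tails accumulate into one weighted raster convolved once per frame — both
exactly equivalent to per-cell convolution passes, which matters because
per-cell intensity factors preclude one global pass.  Zero-mean Gaussian
frame noise of configurable variance (0–255 gray scale) is added last and
never touches the truth table.  The packaged `sample1_config()` fixture
carries the parameters estimated from a real specimen (250 x 250 px, 10
cells of which 3 non-moving, head axes 1.86/2.86 px, normalized noise
variance 8.22e-6 — interpreted as [0, 1]-scale units and converted by
255^2, which reconciles it with the 0–1225 gray-scale sweep).  Cells may
leave the frame freely (no reflection) and drop out of the truth table
while outside.  Frames export as 8-bit multi-page TIFF and tables as CSV
(`write_video()`, `write_truth()`, ...); a thin command-line front end
(`inst/scripts/casa.R`) wraps simulate/detect/track/evaluate.

## Detectors

All static methods work on the complemented frame (heads are dark on a
light background) and share the same post-processing: morphological
closing, dilation and erosion with a 5 px disc, distance-map watershed to
split touching cells, a 20 px^2 minimum blob area, and intensity-weighted
centroids.  The structuring element, minimum area and spot bandwidth are
not specified by the benchmark description, so they are declared package
defaults, exposed in `detector_params()`.  A frame with ~zero gray-level
variance returns no detections instead of an arbitrary threshold.

* `otsu`: global Otsu threshold.
* `adaptive`: Bradley-style local-mean threshold with sensitivity 0.8
  (threshold = window mean x (2 - sensitivity)); the compared pixel value
  is 5x5 box-smoothed so the decision is stable under frame noise without
  blurring the ~6 px head.
* `spot`: a zero-mean negated Laplacian-of-Gaussian matched filter at the
  head scale followed by Otsu on the response.  A clipped (non-zero-mean)
  kernel was considered and rejected: its DC response to the uniform
  background swamps the head peaks and Otsu then segments border-fade
  artifacts rather than cells.
* `edge`: 3x3 median filter, Sobel gradient magnitude (replicate padding —
  zero padding manufactures a frame-wide border rectangle that hole
  filling floods), Otsu on the gradient, edge dilation, hole filling.
* `gmm` (`detect_gmm()`): per-pixel mixture of 3 Gaussians, learning rate
  0.005, background ratio 0.7, 20 training frames that report no
  detections.  Package choices within that frame: a 1/t learning rate
  during training (so cells crossing the first frames average out of the
  background), initial mode sd 40 (fresh modes absorb heavy frame noise),
  an sd floor of 15 (the faint flagellum, contrast ~13, stays
  sub-threshold), model matching at 2.5 sd but the foreground decision at
  4 sd (model matching truncates the learned variance, and at 2.5 sd the
  Gaussian noise tails alone would seed spurious blobs).

## Trackers

`track_cells()` runs four data-association algorithms over one
constant-velocity Kalman core (state x, y, vx, vy; position measurements;
white-acceleration process noise).  Tracks confirm after 2 consecutive
associations, close after 3 consecutive misses, and only confirmed tracks
are reported.  `nn` is exclusive greedy nearest-neighbour in track order;
`gnn` solves the frame's assignment problem exactly; `pdaf` weights all
gated detections per track with detection probability `P_D` and clutter
density; `jpdaf` enumerates the joint feasible association events exactly
within connected clusters of tracks that share gated detections (clusters
above 8 tracks fall back to a hard within-cluster assignment, with a
warning).  Two standard maintenance rules keep the probabilistic
associators healthy: a track whose joint miss probability exceeds 0.8
counts as missed (otherwise lost tracks coast forever inside crowded
gates), and near-coincident (< 3 px) tracks are merged (soft updates let
duplicates coalesce onto one cell).  Gated detections claimed with less
than 0.3 total probability may still initiate new tracks.

The package default process-noise intensity (50 px^2/s^3) is a generic
plumbing default.  For the tracking benchmark the filter is matched to the
swim models it must follow — circular cells turn at ~60 px/s^2 and
hyperactive cells jump ~2.6 px/frame — so `tracking_benchmark()` uses
2000 px^2/s^3 by default.  With the tiny generic value the innovation
covariance declares ordinary maneuvers impossible and the probabilistic
associators disintegrate.

## Evaluation metrics

`ospa()` implements the optimal subpattern assignment distance (cutoff
`c = 20` px, order `p = 2`): the assignment is solved exactly, empty vs
empty is 0, empty vs non-empty is `c`, and the localization/cardinality
components are reported separately.  `match_and_pr()` computes one-to-one
assignment-based precision and recall under a cutoff (default = the OSPA
cutoff, one consistent detection distance scale; with no detections
precision is 1 only when there is also no truth, and recall is vacuously 1
with no truth).  `clear_mot()` scores tracks with correspondence
persistence and under-cutoff assignment at `c_T = 5` px; MOTP is the
*mean* matched distance (the raw sum is also reported — published values
of ~1.4 px identify the statistic as a mean), rates are normalized by the
total truth count, and `MOTA = 1 - (FP + M + MME)` holds as an identity.

## The two benchmarks

`detection_noise_sweep()` simulates the sample-1 fixture, adds frame noise
at 0–1225 gray^2, runs all five detectors, and scores OSPA, precision and
recall on the frames after the 20-frame training window (so the motion
detector is compared on the same frames as everyone else).  Scoring uses a
border ignore band of one kernel half-width, applied match-first: ground
truth drops a cell the moment its head leaves the frame, but the cell's
partially visible body still renders at the border, so an unmatched border
detection cannot fairly count against a detector; band truth is dropped
together with its matched detection so cells straddling the band edge are
not double-counted.
`tracking_benchmark()` simulates the tracking scenario (500 x 500 px, 15
FPS, 10 s, equal mode probabilities, the published kinematic parameter
set) at 20–200 cells, detects with adaptive thresholding on the noiseless
frames using plain binary centroids — their ~1 px quantization error is
the benchmark's localization noise source — and scores each tracker's
measurement-updated track rows with CLEAR-MOT.  Both report tidy tibbles
(one row per condition and replicate, `summarize_sweep()` for means,
`autoplot()` for the standard panels) and are bit-reproducible from the
seed.  The default of 20 replicates mirrors the published design; the
package's own acceptance checks run 5 replicates at 20 and 200 cells and a
5-replicate sweep, sizes chosen so the full suite stays desk-scale.

## What passing tests do and do not show

The generator produces uniform backgrounds, ideal PSF-rendered cells, and
spatially white Gaussian noise.  Real specimens add illumination
gradients, debris, focus drift, non-sperm cells and optical aberrations
that the simulation deliberately omits (by design — the point is exact
ground truth, not photorealism).  Detector rankings measured here therefore
characterize algorithm behaviour under controlled degradation, not
clinical performance.

Two empirical notes from the package's own benchmark runs.  First, at zero
added noise all four static detectors are essentially perfect on the
fixture, so their OSPA ordering is decided by sub-pixel localization
differences and can reorder between seeds; the adaptive detector's
advantage becomes unambiguous once noise is present.  Second, our
exclusive-greedy NN on clean simulated detections performs close to the
optimal assignment (GNN), so the marginal-JPDA tracker — which pays a real
coalescence cost for its soft updates in crowded scenes — ranks below NN
at 200 cells in this implementation, although it clearly beats PDAF and
approaches GNN elsewhere.  Published CASA comparisons that rank JPDAF at
the top alongside GNN used a NN whose false-positive rate was double
GNN's, i.e. a weaker NN variant whose details are not recoverable from the
text.  This limitation is asserted honestly in the test suite rather than
hidden.

## Numerical choices

Half-up rounding for rasterization (independence from pixel-index parity);
Joseph-form covariance updates and explicit symmetrization in the Kalman
core; the ribbon correction constant found by grid search plus golden
-section refinement (tolerance 1e-12); OSPA/matching assignments solved
exactly (over-cutoff pairs share one large cost so the assignment first
maximizes valid pairs); degenerate guards throughout (empty point sets,
single-point tail histories, all-zero kernels, zero-variance frames).
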