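---
title: "Quantifying astrocyte morphology and activity with astroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte morphology and activity with astroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroquant)
```

## Scope and design

`astroquant` quantifies astrocyte structure and signalling from fluorescence
imaging and slice electrophysiology. Because raw two-photon/confocal
recordings of this kind are rarely shareable, every stage is paired with a
synthetic-data generator that emits the same input with known ground truth;
the test suite and the demo pipeline exercise the analysis end to end on
those generated inputs. The generators are first-class, tested code, not
fixtures: each is a pure function of `(parameters, seed)`.

## Spatial entropy and statistical complexity

A 2D pattern is summarized by a per-pixel probability distribution over
scale/orientation features and scored in the entropy-complexity plane.

**Feature densities from shearlets.** The image is decomposed with a
cone-adapted Meyer-type discrete shearlet frame (`build_system()`,
`transform()`). Scale $j$ (1 = coarsest) carries shear indices
$k \in [-2^{j-1}, 2^{j-1}]$ in each of two frequency cones, with the two
diagonal windows glued across cones, so orientation resolution doubles with
spatial frequency; a lowpass band completes the tiling. The squared
frequency windows sum to one at every frequency bin (renormalized
numerically to kill round-off), so the frame is Parseval-tight:
`inverse_transform()` reconstructs to better than $10^{-8}$ and circular
translation commutes with the transform. Squared coefficient magnitudes are
smoothed with a Gaussian of scale-dependent width
$\sigma_j = 8 / 2^{j-1}$ pixels (the kernel roughly tracks the shearlet's
spatial support; only "scale-dependent" is prescribed by the method) and
normalized per pixel:

$$P_k(x, y) = E_k(x, y) \Big/ \sum_{k'} E_{k'}(x, y).$$

Two interpretation choices are deliberate and configurable:

* the normalization runs over **all** directional features (scales and
  shears), which is the only reading that makes $P$ a single density over
  the full feature set;
* the **lowpass band is excluded** from the density by default — it encodes
  local offset, not structure (`include_lowpass = TRUE` restores it);
* pixels whose total power falls below $10^{-12}$ of the mean are given the
  uniform density and flagged (`uniform_fallback`), since the ratio is
  undefined at zero.

**Entropy and complexity.** With $N$ features,
$H_s = -\sum_i P_i \log_2 P_i / \log_2 N \in [0, 1]$, and the statistical
complexity is $C = Q_{JS} \cdot H_s$ where
$Q_{JS} = J[P, P_e] / J_{max}$ is the Jensen-Shannon divergence from the
equiprobable $P_e$, normalized by its closed-form maximum at a degenerate
distribution. $C$ vanishes both for perfect order and full randomness and
peaks in between. We take $S_{max} = \log_2 N$; entropies are in bits
throughout. Note $J_{max}$ is evaluated in closed form (the maximizer is
degenerate), not by numerical search.

`map_entropy_complexity()` evaluates both quantities at every pixel and
summarizes over a cell mask. The default reduction is the mean (median
available); per-cell values can be averaged over an astrocyte mask or the
full frame — both are supported and the mask-mean is the default. Non-square
images are mirror-padded for the transform and the maps cropped back.

**Calibration textures.** `gen_pattern()` emits oriented single-frequency
stripes (ordered), i.i.d. noise (disordered) and blurred random branching
trees (structured randomness). Across seeds the package reproduces the
expected ordering — stripes lowest in both $H_s$ and $C$, noise highest in
$H_s$ with depressed $C$, branching intermediate in $H_s$ with the highest
$C$. One caveat: even for i.i.d. noise, the per-pixel density is not close
to uniform in total-variation terms, because expected band power scales with
window mass and the band-limited coefficient fields leave few independent
samples per smoothing disk; $H_s$ of noise settles near 0.9 rather than 1.
The calibration tests therefore assert the ordering, which is robust, rather
than closeness to the uniform density.

## Morphometry

**Branch mask.** Each z-plane passes through Perona-Malik anisotropic
diffusion (10 iterations, conduction scale at the 90th gradient percentile,
step 0.15 — the filter family is standard, the parameters are this
package's own defaults),
then the maximum projection is thresholded against a 31-px local-mean
surface plus 2% of the intensity range, and objects under 20 px are removed.
A constant image yields an empty mask with a flag rather than an error.

**Sholl profile.** Intersections are counted as contiguous foreground runs
along discretized circles (angular step under half a pixel, run-length
merging with cyclic wrap, so a thick branch counts once). The soma boundary
is not observable directly; `n_primary` is read at the first radius where
the circle exits the foreground blob containing the soma. `distal_counts`
are the counts beyond the profile peak, and the full profile is returned so
any radial band can be re-tested. Default step: 2 um. Discretization makes
counts rotation-tolerant only to about one intersection, which the property
tests encode.

**Leaflet volume fraction.** Along a 45-um line from the soma,
$GV = (F - F_0) / (F_{max} - F_0)$ with $F_{max}$ the mean over an
unsaturated soma ROI (taken as 100% cytosol in the excitation volume) and
$F_0$ the mean over an astrocyte-free background ROI. Values are clipped to
$[0, 1]$ with the clip count reported; saturated somata and
$F_{max} \le F_0$ are errors. The leaflet summary averages positions past
the soma edge (auto-detected as the first half-max crossing unless given)
and outside caller-marked branch intervals, as a percentage. The measure is
invariant under affine intensity rescaling by construction.

## Dye coupling

Distances between soma centroids use the calibrated voxel sizes in all
three axes; intensities are normalized to the patched soma. The length
constant comes from the slope of the least-squares line in semilog space
($C_\lambda = -1/\text{slope}$), the procedure standard in dye-coupling
work; a direct
nonlinear fit of $I_0 e^{-d/C_\lambda}$ is available as a cross-check. The
patched cell itself is excluded from the fit by default (configurable) —
including its $d = 0$, $I = 1$ point is a modelling choice the method
leaves open. The synthetic generator draws distances uniformly on
5-100 um and applies multiplicative lognormal noise; intensities are
clipped to $(0, 1]$ to honor the normalization invariant, which is inactive
in practice at the default $I_0 = 0.8$.

## Calcium events

The movie chain is: per-pixel dark-noise median subtraction; an optional
denoising hook (`denoise` argument — identity by default; block-matching
denoisers are out of scope and pluggable); phase-correlation registration
with subpixel refinement by local DFT upsampling; then per-pixel dF/F with
a two-pass baseline: a 60-s, 3rd-order Savitzky-Golay smooth gives a
provisional baseline, supra-threshold transients are excised (with a
2-frame guard band), the gaps are linearly interpolated, and a 100-s filter
produces the final baseline. Window lengths are converted to odd frame
counts at the calibrated frame interval (1 frame/s by default).

Detection binarizes $\Delta F/F > k \hat\sigma$ with
$\hat\sigma = 1.4826 \times \mathrm{MAD}$ per pixel and $k = 2.5$ by
default — only a "statistical threshold" is prescribed by the protocol
class, so $k$ is explicit configuration. Active pixels group within frames
(8-connectivity) and link across consecutive frames sharing a pixel
(`gap_frames` adds tolerance; 0 by default). Per event: `s_max` is the area
of the union-over-time footprint (the largest single-frame area is also
reported, since "maximal projection" admits both readings), the integral is
voxel count x pixel area x frame interval, and the duration spans first to
last active frame. The exclusion filters keep events with integral
$\ge 4\ \mu m^2 s$, $S_{max} \ge 10\ \mu m^2$ and duration $\ge 2$ s —
thresholds are written as "less than" exclusions, so boundary values are
kept; the 2-s floor is also the astrocyte/neuron separation criterion.

Power-law exponents are estimated by log binning: log-spaced bins,
per-bin density `count / (width * n)`, empty bins dropped, straight line in
log-log space, $\alpha = -$slope with the regression's standard error. For
a pure power law this estimator is exactly linear in log-log space when
binned geometrically, which the tests exploit with an exact constructed
histogram. Twelve bins by default.

**Generator.** `gen_ca_movie()` plants elliptical events whose areas and
durations are inverse-CDF power-law draws above the filter floors
(10 um^2, 2 s) — so the filters cannot bias exponent recovery — on a
baseline of 100 counts with a slow (5%) multiplicative drift and shot-like
noise (sd $\propto \sqrt{F}$); the time course rises over one frame and
decays exponentially, truncated at half amplitude so the supra-threshold
support equals the planted duration. Events are placed with disjoint padded
bounding boxes (rejection sampling) so the planted count is conserved;
area/duration draws are truncated (20% of the field, a quarter of the
recording) so footprints fit, which slightly thins the extreme tail — the
exponent-recovery checks therefore use direct untruncated samples. Defaults
(64 x 64 px at 0.5 um/px, 300 frames, 15 events) are deliberately desk-scale
so a 20-movie recall/false-positive suite runs in minutes; what a green run
establishes is correctness of the chain on well-separated events above
realistic noise, not performance on overlapping events, photobleaching or
neuronal contamination, which the generator does not emulate.

## Electrophysiology

* `measure_ik()`: the K+ current is read 200 ms after the stimulus (past
  the field-potential and transporter currents, which die within 100 ms)
  and the tail from that point is fitted with $A e^{-t/\tau}$ — a
  log-linear fit provides the start values and `nls` refines them; on
  noiseless data the log-linear solution is already exact and is kept when
  `nls` cannot improve a zero residual. Non-decaying tails are flagged
  invalid rather than reported.
* `isolate_fifth()` subtracts the 4-stimulus response from the 5-stimulus
  response pointwise, isolating the current evoked by the 5th stimulus of
  a 50-Hz train.
* `fepsp_metrics()` measures negative-going fEPSPs: baseline-to-peak
  amplitude, 20-80% rise slope with linearly interpolated crossings, fiber
  volley amplitude in its early window (0-3 ms; fEPSP window 3-45 ms,
  both configurable), and paired-pulse ratio amp2/amp1 at the 50-ms
  interstimulus interval.
* `fit_gompertz()` fits $y = a e^{-e^{-k(x - x_c)}}$ by nonlinear least
  squares, initialized with $a_0 = \max y$, $x_c$ at half-maximum, and
  $k_0 = e \cdot \max(\Delta y/\Delta x) / a_0$ (from the identity that the
  curve's maximum slope, at $x = x_c$, is $a k / e$). The reported
  `max_slope` is computed from the fitted parameters and checked against
  numerical differentiation in the tests.
* `ltp_magnitude()` is the ratio of the mean rising slope in a
  post-induction window (47-60 min by default; any window can be passed,
  e.g. 5-15 min for the initial phase) to the mean over the 20-min
  baseline.

The trace generator plants all of these quantities exactly: the slow
current's amplitude and decay constant, the 5th/1st amplitude and tau
ratios (the 5th-stimulus amplitude is back-computed so the 200-ms
measurements reproduce the requested ratio exactly), Gompertz parameters,
and a post-induction plateau or exponential sag between an early and a late
potentiation level. High-frequency-stimulation protocol constants are
metadata; induction itself is not simulated.

## Determinism and the demo pipeline

`run_demo(seed)` generates one input of every kind (per-stage seeds derived
from the master seed), runs all stages, and returns a long-format table
(`sample_id`, `metric`, `value`, `units`, `stage`, `config_hash`, `seed`).
The same seed and configuration yield an identical table; stage failures
are recorded and do not abort the remaining stages. `default_config()`
carries the calibration (0.5 um/px, 1 s/frame) and all stage defaults;
unknown fields are rejected, and the configuration hash is embedded in
every output row for provenance.

## Numerical choices and limitations

* All randomness flows through a seed argument; generators restore the
  caller's RNG state.
* Gaussian smoothing and the shearlet windows use periodic (FFT)
  boundaries; for cells near the frame edge, power can wrap — keep a margin
  or mirror-pad.
* The noise models (additive Gaussian for morphology and dark frames,
  multiplicative lognormal for coupling, shot-like for movies) are
  conventions chosen for simplicity; real acquisition noise statistics
  vary by instrument and are not modelled.
* Event linking uses strict footprint overlap; a one-frame dropout splits
  an event unless `gap_frames` is raised.
* The Sholl count is a crossing count, not a branch count: a branch
  tangent to a circle can contribute twice at adjacent radii
  (discretization tolerance of one).
* No TIFF I/O is bundled: inputs are in-memory arrays (or CSVs for tabular
  records), and all images in the documentation are generated by code.
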