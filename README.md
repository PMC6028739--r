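# astroquant

Quantitative analysis of astrocyte morphology and activity for slice
imaging and electrophysiology.

Astrocytes remodel in disease: their micron-scale branches atrophy while
their nanoscopic leaflets (below the diffraction limit) may not, their
gap-junction coupling weakens, and their spontaneous Ca²⁺ activity shifts
toward smaller events. Detecting these changes requires a battery of
quantitative measures that are usually scattered across ad-hoc scripts.
`astroquant` packages them as one tested R pipeline:

* **Spatial entropy–complexity mapping.** Images are decomposed with a
  cone-adapted Meyer shearlet tight frame; the per-pixel normalized band
  power `P_k(x,y) = E_k / Σ E_k` is treated as a probability distribution
  over scale/orientation features and scored by normalized Shannon entropy
  `H_s = S[P]/log₂N` and statistical complexity `C = Q_JS · H_s`, where
  `Q_JS` is the normalized Jensen–Shannon divergence from the equiprobable
  distribution. Ordered textures score low in both, pure noise scores high
  `H_s` / low `C`, and branching patterns — astrocyte-like structured
  randomness — maximize `C`.
* **Sholl morphometry** on adaptively thresholded, anisotropic-diffusion
  filtered projections: intersections of concentric circles with the branch
  mask, primary-branch count, enclosing radius, distal counts.
* **Leaflet volume fraction** from fluorescence line profiles,
  `GV = (F − F₀)/(F_max − F₀)`, soma = 100 %, background = 0 %.
* **Dye-coupling decay**: `I(d) = I₀ exp(−d/C_λ)` fitted in semilog space
  over 3D distances to coupled somata.
* **x-y-time Ca²⁺ events**: dark-noise subtraction, subpixel registration,
  two-pass Savitzky–Golay ΔF/F baselines with transient exclusion,
  statistical thresholding, 3D connected-component events, size/duration
  filters (≥ 4 µm²·s, ≥ 10 µm², ≥ 2 s), frequency density, and power-law
  exponents `P(x) ~ x^(−α)` by log-binned regression.
* **Electrophysiology**: K⁺ current at 200 ms with mono-exponential
  `τ_decay`, 5-minus-4 stimulus isolation, fEPSP amplitude and 20–80 %
  rise slope, paired-pulse ratio, Gompertz input–output fits
  (`y = a·exp(−exp(−k(x−x_c)))`, max slope `ak/e`), and LTP magnitude
  (47–60 min post-induction vs baseline).
* **Synthetic data generators** for every input — branching astrocyte
  stacks with a leaflet haze, Ca²⁺ movies with planted power-law events,
  coupling records, voltage/current traces — each a pure function of
  `(parameters, seed)` with exact ground truth attached, so every stage is
  testable without any raw recordings.

## A worked example

```r
library(astroquant)

# a synthetic astrocyte: 6 straight 40-um processes, 3.4% leaflet haze
ast <- gen_astrocyte(n_rays = 6, ray_length_um = 40, leaflet_vf = 0.034,
                     seed = 42)
mask <- make_branch_mask(ast)
sholl_profile(mask)
#> Sholl profile: 27 radii (step 2.0 um), primary = 6, peak = 6, enclosing = 40.0 um
vf_from_synthetic(ast)$mean_leaflet_vf
#> [1] 3.4

# dye-coupling decay: 50 cells, true length constant 33 um, 10% noise
fit_coupling(gen_coupling_set(33, n = 50, noise_sd = 0.1, seed = 1))
#> coupling fit (semilog): C_lambda = 33.37 um, I0 = 0.793, n = 50, r2 = 0.986

# entropy-complexity of a branching texture
map_entropy_complexity(gen_pattern("branching", 128, 1))
#> entropy-complexity map 128x128: mean H_s = 0.534, mean C = 0.302 (28 features)
```

The Sholl profile counts exactly the six planted processes at every radius
inside their length, enclosing radius 40 um; the volume-fraction profile
returns the planted 3.4 % haze; the coupling fit recovers the 33-um length
constant within the 10 % noise; and the branching texture sits in the
high-complexity region of the entropy–complexity plane (compare
`gen_pattern("periodic", ...)` ≈ (0.09, 0.07) and
`gen_pattern("noise", ...)` ≈ (0.88, 0.14) for the same seed).

The full chain on a synthetic Ca²⁺ movie:

```r
mv  <- gen_ca_movie(n_events = 15, alpha_area = 2.7, seed = 4)
m   <- subtract_dark_noise(mv$movie, mv$dark_frames)
dff <- compute_dff(m, mv$frame_interval, mv$pixel_size)
ev  <- filter_events(detect_events(dff))
nrow(ev)        # 15: every planted event recovered, no false positives
set.seed(1)
fit_power_law(sample_power_law(1e4, 2.7, 10), x_min = 10)
#> power-law fit: alpha = 2.737 +/- 0.110 (n = 10000, x_min = 10)
```

`run_demo(seed = 1)` runs all of the above plus the electrophysiology
battery and returns one long-format table; with seed 1 it reports, among
others, `tau_decay_ik1 = 2.5 s`, `ik5_over_ik1 = 0.72`,
`io_max_slope = 7.33` (= a·k/e for a = 3.32, k = 6) and
`ltp_magnitude = 1.73` — the generators' planted values, recovered by the
measurement code.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the demo pipeline from scratch against the installed package
(all inputs generated from the given seed), writes the aggregate metric
table next to the JSON output, and exits non-zero on failure.

## Package layout

* `R/` — generators (`gen_*`), shearlet transform (`build_system`,
  `transform`, `inverse_transform`, `local_power_density`),
  entropy/complexity, morphometry, coupling, Ca²⁺ events, ephys metrics,
  and the demo pipeline.
* `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are built in code.
* `vignettes/astroquant-methods.Rmd` — the model, parameter and design
  documentation.
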