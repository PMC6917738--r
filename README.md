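# filnet

Quantitative image analysis of treadmilling filament networks.

Reconstituted cytoskeletal systems — prototypically the bacterial
cell-division proteins FtsZ and FtsA, with or without crosslinkers such as
ZapA, self-organizing on supported lipid bilayers — form dynamic networks
of curved, treadmilling filament bundles that are imaged by TIRF
time-lapse microscopy. filnet turns such calibrated movies into the
quantities that characterize these networks, for biophysicists and
quantitative microscopists working on cytoskeletal self-organization:

| quantity | estimator |
|---|---|
| bundle width δ (µm) | adaptive threshold → despeckle → Euclidean distance map → 2 × mean of strict 1D ridge peaks |
| mean curvature k (µm⁻¹) | structure-tensor orientation field; k = \|∇θ\| with nematic unwrapping; exponential MLE of the per-frame distribution |
| spatial correlation length ρ (µm) | S(r) = ⟨cos 2(θᵢ−θⱼ)⟩ over window pairs; ρ from the S = 0.5 crossing |
| reorganization time τ (s) | Pearson correlation of 3×3-block-mean frames vs lag; mono-exponential half-time |
| treadmilling velocities ν± (nm/s) | spatiotemporal low-pass → consecutive-frame differences (growth/shrink channels) → blob detection → exact min-cost linking → per-track speed |
| turnover (s) | FRAP fit I(t) = a(1 − e^(−bt)); single-molecule residence times by truncated exponential MLE with photobleaching correction k_obs(Δ) = k_off − ln(1 − p)/Δ |
| ultrasensitivity | Hill fit y(c) = y₀ + (y_max − y₀)cⁿ/(EC50ⁿ + cⁿ) by variable projection, with stratified case-resampling bootstrap CIs |

A seeded synthetic-movie generator (`generate_network_movie()`,
`generate_frap_movie()`, `generate_single_molecule_movie()`,
`generate_titration_table()`) renders treadmilling ribbon networks with a
Gaussian PSF and a Poisson + read-noise camera model and records the true
value of every estimand, so every estimator in the package is validated by
parameter recovery. See the vignette
(`vignettes/filament-network-analysis.Rmd`) for the models, parameter
defaults, and design decisions.

## Worked example

Generate a synthetic steady-state network, measure its bundle width, and
fit a steep dose–response titration with bootstrap confidence intervals:

```r
library(filnet)

p <- network_params(duration = 30, field_size = 128 * 0.108)
g <- generate_network_movie(p, seed = 1)
ws <- width_series(g$movie, analysis_config(min_peak_px = 2))
attr(ws, "width_ss_um")
#> [1] 0.6489585

d <- generate_titration_table(c(0.63, 0.77, 13.86, 0.81),
                              c(0, 0.1, 0.5, 0.75, 1, 1.5, 3, 6),
                              noise_sd = 0.02, replicates = 3, seed = 1)
fit <- bootstrap_ci(fit_hill(d), n_boot = 199, seed = 1)
fit
#> Hill fit: y0 = 0.6326, ymax = 0.7752, n_H = 8.116, EC50 = 0.8246 uM (n = 24)
#>   90% bootstrap CIs: n_H [4.82, 62.04], EC50 [0.7589, 0.8992]
```

The measured width (0.65 µm) reads out the generated 0.6 µm ribbon
convolved with the PSF through the distance-map estimator. The titration
was generated from a Hill curve rising from 0.63 to 0.77 with EC50
0.81 µM and Hill coefficient 13.86: the EC50 comes back within a few
percent with a tight CI, while the Hill coefficient — weakly identified
for near-step responses, by construction — is recovered to its order of
magnitude with an accordingly wide CI. `tidy()`/`glance()` methods and
`autoplot()` are available for the fit objects;
`run_pipeline(movie, config, out_dir)` writes per-stage CSVs and a JSON
summary for batch work.

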