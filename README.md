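# tensionfret

Quantifying molecular tension across junctional adapter proteins with
genetically encoded FRET tension sensors — from raw photon histograms and
three-channel acquisitions to image-grouped effect sizes.

Desmosomes anchor the intermediate-filament cytoskeletons of neighbouring
epithelial cells, with desmoplakin (DP) as the obligate adapter between the
desmosomal plaque and the filaments. A tension sensor module — a FRET pair
joined by an elastic peptide — inserted into DP reports mechanical load:
tension stretches the linker and lowers FRET. `tensionfret` implements the
complete quantification pipeline for such experiments, for microscopists and
mechanobiologists who have lifetime (FLIM) or sensitized-emission data of
punctate junctional structures:

- **FLIM-FRET**: per-pixel TCSPC photon histograms are segmented into
  desmosomal puncta, summed decays are fitted by Poisson maximum likelihood
  (`A e^{-t/τ}`, amplitude profiled out, fit starting 0.56 ns after the peak
  bin), and FRET efficiency follows `E = 1 − τ_DA / τ̄_D` against a matched
  donor-only lifetime (presets: 2.94 / 2.98 / 2.52 / 2.55 ns).
- **Sensitized emission**: flat-field correction, rolling-ball background
  subtraction (50 px ball), linear spectral de-mixing with measured
  cross-talk factors ε (presets for mTFP1/mEYFP and YPet/mCherry), and the
  ratiometric index `I = 100·F_cor / (D_cor + F_cor)` per punctum.
- **Recoil tracking**: pre/pull/post micropipette-pull sequences are
  registered with a control-point homography, puncta are matched by
  minimum-total-displacement bipartite assignment, and each track gets a
  recoil distance `d_r`, a robust local contact slope, and the acute recoil
  angle `α_r = tan⁻¹((m_r − m_c)/(1 + m_r m_c))` with the printed
  inclusion rules (≥ 1 µm recoil, `d_r` ≤ 10 µm, ≥ 3 slope points,
  SE ≤ 9°, 45° parallel/perpendicular split).
- **Statistics**: the sensor-vs-control difference `Δ = ctrl − TS`
  (positive = tension) estimated with a per-image random intercept,
  `value ~ isTensionSensor + (1 | imageNumber)`, drug-interaction variants,
  distance/angle-binned contrasts against a pooled control, KS comparisons
  and per-image boxplot summaries.
- **Synthetic scenes**: every stage has a ground-truth-labelled generator
  (decays, FLIM stacks, three-channel scenes, pull sequences, grouped
  tables), so the whole pipeline is testable without microscope data.

## Worked example

```r
library(tensionfret)

# a simulated TCSPC decay at the mTFP1-F40-mEYFP donor-only lifetime
d <- simulate_decay(lifetime = 2.52, photon_budget = 1e4, seed = 1)
fit_decay_ml(d)
#> <decay_fit> tau = 2.5221 ns (7831 photons, start bin 14)

# a sensor punctum whose donor lifetime dropped to 2.0 ns is under load:
fret_efficiency(2.0, 2.52)
#> [1] 0.2063492

# grouped two-arm experiment, 20 images/arm x 30 puncta, true delta = 3
tab <- simulate_grouped_fret_table(n_images_per_arm = 20,
                                   puncta_per_image = 30, true_delta = 3,
                                   image_sd = 2, punctum_sd = 4, seed = 42)
fit_grouped_difference(tab)
#> <grouped_difference> delta = 3.959 [2.764, 5.155] (95% CI), p = 8.57e-11
#>   1200 puncta / 40 images; image SD 1.784, residual SD 4.016
```

The fitted lifetime recovers the simulated 2.52 ns within photon-shot
precision; the mixed-model estimate covers the simulated Δ = 3 index units,
and its interval accounts for the shared per-image variability (a pooled
t-test interval would be misleadingly narrow). `recoil_angle(1, 0)` gives
45°, `recoil_angle(Inf, 0)` gives 90° — recoil perpendicular to a
horizontal junction.

A full synthetic run (simulate → FLIM → tracking → statistics) is one call:

```r
res <- run_pipeline(run_config(seed = 3, out_dir = "demo_run"))
```

or from the shell: `Rscript inst/cli/tensionfret run --out-dir demo_run`.

## Layout

- `R/` — implementation (decay fitting, segmentation, ratiometric chain,
  tracking, statistics, generators, I/O).
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (grid search, permutation enumeration, ECDF supremum).
- `vignettes/tension-fret-methods.Rmd` — models, assumptions, parameter
  choices and known limitations.
- `inst/cli/tensionfret` — command-line entry point.
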