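---
title: "Methods: FRET tension-sensor quantification for junctional puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET tension-sensor quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensionfret)
```

This vignette is the package's account of its science: the models each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic generators emulate (and do not), and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## The measurement problem

A genetically encoded tension sensor joins a FRET donor and acceptor with
an elastic peptide. Mechanical load extends the peptide, increasing the
fluorophore separation and lowering FRET. Two readouts are supported:

1. **Lifetime (FLIM-FRET).** FRET opens a non-radiative decay channel for
   the donor, shortening its fluorescence lifetime. With the matched
   donor-only lifetime $\bar\tau_D$ as reference,
   $E = 1 - \tau_{DA}/\bar\tau_D$. Efficiency from lifetimes is
   concentration-independent, which matters for overexpressed constructs.
2. **Sensitized emission.** Three epifluorescence channels — donor
   excitation/donor emission $D$, donor excitation/acceptor emission $F$,
   acceptor excitation/acceptor emission $A$ — yield, after spectral
   cross-talk correction, the ratiometric index
   $I = 100\,F_{cor}/(D_{cor}+F_{cor})$. $I$ is a within-experiment proxy,
   not an absolute efficiency; all inference is on *differences* between a
   sensor and a matched truncated control that cannot transmit force.

The analysis unit is the punctum: one segmented desmosomal spot at a
cell–cell junction. Tension is reported as $\Delta = \mathrm{ctrl} -
\mathrm{TS}$ (efficiency or index units), so positive values mean load.

## TCSPC decay model and the Poisson ML fitter

Per-pixel TCSPC data are photon counts $k_i$ in time bins $t_i$. Decays
summed over a punctum or mask are modelled as a single exponential
$\mu_i = A e^{-t_i/\tau}$ with independent Poisson counts. The fit window
starts 0.56 ns after the first bin attaining the maximal count, which
suppresses the instrument response and fast autofluorescence; for this
reason the default model carries **no additive background term** and no
IRF convolution (a constant-background variant and an optional Gaussian
IRF exist for robustness checks, both off by default).

The amplitude is profiled out of the Poisson likelihood analytically
($\hat A(\tau) = \sum k_i / \sum e^{-t_i/\tau}$), leaving a 1-D problem in
$\tau$ solved by a deterministic coarse grid (60 points on [0.1, 10] ns)
followed by golden-section refinement — repeated fits are bit-identical,
and the tests verify the optimum against a brute-force likelihood grid at
0.001 ns resolution. Fits with fewer than 2 photons in the window are
flagged non-converged; estimates at the box bounds are flagged.

**Time axis.** Neither acquisition system's bin count nor repetition
period is prescribed, so the simulator defaults to 256 bins over 12.5 ns
(an 80 MHz-like repetition rate, typical of Ti:Sapphire two-photon
sources). Both are configurable; the fitter takes whatever binning the
data carry.

## Punctum segmentation

Two modes mirror the two experimental geometries:

- **Auto** (whole-image): difference-of-Gaussians band-pass tuned to
  feature diameters 3–10 px with $\sigma = d/2.355$ (the FWHM↔σ
  convention; only the diameter range is prescribed), threshold at
  mean + 1 SD **of the filtered image** (the filtered reading of "after
  band-pass filtering"; this also makes the segmentation exactly invariant
  to constant offsets), then assignment of connected supra-threshold
  pixels to the nearest local intensity maximum.
- **Manual-masked** (junction masks drawn by hand): Gaussian blur
  $\sigma = 3$ px inside the mask, then "connected bright regions". The
  brightness criterion is a lab convention that is not quantified anywhere,
  so the package uses an Otsu threshold computed within the mask on the
  blurred image, exposed as a parameter.

Nearest-local-maximum assignment is deterministic hill-climbing with
8-connectivity and pointer jumping; plateau ties break toward the smallest
column-major pixel index, making labels reproducible. Regions smaller than
9 px are removed in both modes. The acceptor-channel segmentation of the
ratiometric pipeline reuses this machinery with its threshold defined as
mean + 4 SD over a user-supplied background region of the monolayer (the
background region is an explicit input; a lowest-decile convenience
heuristic exists but is never a default).

## Ratiometric chain and the de-mixing convention

Processing order is fixed: dark/flat-field correction per channel, then
rolling-ball background subtraction (grey-scale opening with a spherical
structuring element, default diameter 50 px), then per-pixel linear
de-mixing, then segmentation, then indices. The shipped cross-talk matrix

$$M = \begin{pmatrix} 1 & \varepsilon_{FD} & \varepsilon_{AD} \\
\varepsilon_{DF} & 1 & \varepsilon_{AF} \\
\varepsilon_{DA} & \varepsilon_{FA} & 1 \end{pmatrix}$$

is interpreted as the **forward** mixing operator, observed = $M\cdot$true,
so de-mixing solves corrected $= M^{-1}\cdot$observed. Taken literally, a
positive-off-diagonal matrix applied to observations would *add*
cross-talk rather than remove it; the inverse reading is the physically
sensible one and is the default, with the literal product available behind
`interpretation = "direct"` for comparison. Round-trip tests (forward then
inverse with both shipped ε sets) hold to ≤ 1e−8.

Per-punctum indices are computed from **summed** corrected intensities
over the punctum's pixels, not means of per-pixel indices: summing is
photon-weighted and matches the total-intensity phrasing of the dim-punctum
filter (ΣA$_{cor}$ < 5000 a.u. for the mTFP1/mEYFP constructs, < 2000 for
YPet/mCherry; camera-specific values exposed as configuration). Negative
corrected intensities are retained — clipping would bias ΔI — and
out-of-range indices are flagged by the extreme-value filter instead.
Channel-misalignment exclusion is a manual QC input honoured per punctum,
never inferred.

## Recoil geometry

Pull sequences are registered with a projective map fitted to 6–10 manual
control points by normalised DLT. The map only aids **matching**: puncta
at maximal pull are matched to their post-relaxation positions in the
registered frame, but recoil vectors are differences of the original
coordinates, $d_r = \|x_{post} - x_{pull}\|$. Matching minimises total
Euclidean displacement over one-to-one assignments with a 15 µm gate
(covering the 10 µm analysis window with margin; the gate and tie policy
are not prescribed — when set sizes differ, maximum feasible cardinality
is matched first, then cost). The assignment solver is checked against
exhaustive permutation enumeration on instances up to 8 puncta.

The local contact slope $m_c$ at a punctum is a bisquare-IRLS line through
the punctum and neighbours within 4 µm, computed in a rotated frame chosen
from the principal axis so vertical contacts produce no infinities; the
slope SE is propagated to degrees and fits with < 3 points or SE > 9° are
flagged unreliable. The recoil angle is the acute angle between the recoil
line and the contact line, evaluated in angle space (equivalent to
$\tan^{-1}((m_r-m_c)/(1+m_r m_c))$ away from the vertical singularity):
0° parallel, 90° perpendicular, split at 45° for orientation classes.
Track filters flag rather than delete: recoil < 1 µm, $d_r$ > 10 µm,
isolation (< 2 neighbours within 10 µm), and direction mismatch (> 60°
from the neighbour-mean recoil direction; "substantially different" and
"isolated" are unquantified conventions, both configurable). The ≥ 1 µm
recoil criterion is applied per punctum; whether it was meant per junction
region is ambiguous, and the per-punctum reading is the stricter one.

## Grouped statistics

Puncta from one image share illumination, focus and local biology, so they
are not independent. The estimator is a linear mixed model with a
per-image random intercept, `value ~ isTensionSensor + (1 | imageNumber)`,
fitted by REML (lme4), reporting $\Delta = -\beta_{TS}$ with Wald CIs and
normal-approximation p-values. A Satterthwaite-style small-sample
correction would change little at ≥ 15 images per arm (the design scale
the coverage tests use); the degrees-of-freedom method is therefore a
documented deviation, and boundary variance estimates (image variance 0)
are reported as 0 with a flag, at which point the estimator coincides with
pooled OLS (verified to 1e−5 in tests). Binned contrasts refit the model
per bin of $d_r$ or $\alpha_r$ against the entire un-binned control pool —
per-bin 68% intervals, control mean with 95% — rather than one model with
bin factors, mirroring how binned sensor data are compared to pooled
controls. The 68% level is implemented as a symmetric Wald interval.
Distribution comparisons use the two-sided two-sample KS test; boxplot
summaries reduce to per-image medians first, with whiskers at the last
datum within 1.5×IQR.

## What the generators emulate — and what they do not

- `simulate_decay`: mono-exponential expectations plus constant
  background, independent Poisson counts. No IRF by default (the 0.56 ns
  offset justifies pure exponentials), no afterpulsing, no pile-up.
- `simulate_flim_scene` / `simulate_three_channel_scene`: puncta as
  isotropic Gaussian profiles truncated at 3σ (punctum shape is not
  described anywhere; Gaussians are the standard idealisation), uniform
  background, Poisson or Gaussian noise, forward-mixed channels with
  vignette and dark offset. Pixel-size defaults follow the two acquisition
  geometries (70.85/512 ≈ 0.138 µm and 61.51/512 ≈ 0.120 µm). Overlapping
  puncta with conflicting ground truth are rejected rather than blended.
- `simulate_pull_sequence` warps punctum **centres** by the homography and
  re-derives everything from the point process, so no interpolation
  artefacts enter the ground truth. The tension response is a minimal
  monotone model, $\Delta I = g\,\min(d_r, 10\,\mu m)\,\sin^p\alpha_r$ —
  a stand-in consistent with distance- and angle-dependent loading, not a
  mechanistic claim. The ground-truth recoil angle is measured against the
  junction polyline *after* warping, because the contact deforms with the
  monolayer and the puncta-based slope estimate sees the deformed contact.
- `simulate_grouped_fret_table`: normal per-image intercepts and normal
  residuals — exactly the mixed model's assumptions, which is the point:
  it verifies the estimator, not the biology.

Consequently a green suite establishes *algorithmic* correctness —
segmentation determinism, ML optima, matching optimality, unbiased index
recovery, CI coverage under the stated noise model — and does **not**
establish robustness to real-data features the generators omit:
autofluorescent debris, photobleaching, non-exponential decay mixtures,
chromatic misregistration, or keratin-network mechanics. The end-to-end
angle-recovery property (±2° for ≥ 95% of unflagged tracks) is checked on
scenes whose puncta lie on the contact with 0.02 µm transverse scatter;
larger scatter degrades the local slope estimate for any estimator — an
irreducible scene property, not an implementation defect.

## Numerical choices and degenerate inputs

- Gaussian convolutions renormalise kernel mass at borders, so constant
  images are exact fixed points; a flat image segments to zero puncta via
  an explicit featurelessness guard (the DoG of a constant is rounding
  noise).
- Rolling-ball morphology uses replicate padding; opening is exact for
  affine images in the interior, with edge effects within a ball radius of
  the border — visible on steep gradients, negligible on the 100-px-scale
  backgrounds the filter targets.
- Peak bin = first bin attaining the maximum (ties occur at low counts).
- Coordinates: 0-based pixel indices, physical position
  (index + 0.5)·pixel size; x = columns, y = rows, µm and ns throughout.
- Assignment costs gate infeasible pairs with a surrogate larger than any
  feasible total, which enforces maximum-cardinality-then-minimum-cost.
- Efficiencies and indices are never clamped; range filters flag.

## File formats

Stacks and channel images serialise to documented plain-text formats (one
whitespace row per time-bin page plus a JSON sidecar carrying bin width
and pixel size) because no TIFF codec is available in the supported
dependency set; the page-per-bin structure and sidecar metadata match what
a TIFF exporter would carry, and readers validate page counts and sidecar
fields. Tables are schema-versioned CSV; configurations are JSON and
round-trip losslessly. The demonstration pipeline
(`run_pipeline`) chains simulate → FLIM → tracking → statistics with
filter accounting (rows in = rows out + flagged) asserted on every run.

## Known limitations

Single-exponential decays only (no phasor or multi-exponential analysis);
no acceptor-photobleaching or G-factor-calibrated absolute E-FRET; no
automated pipette detection or dense optical flow — junction geometry
comes from puncta positions alone; no multiple-testing correction across
bins (none is applied in the workflow this implements); Wald rather than
Satterthwaite intervals, as discussed above.
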