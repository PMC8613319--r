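---
title: "Quantifying metal artifact reduction in a hip arthroplasty CT phantom"
author: "phantoMAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metal artifact reduction in a hip arthroplasty CT phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phantoMAR)
```

## The problem

CT follow-up after total hip arthroplasty (THA) is degraded by metal
artifacts: beam hardening, scatter and photon starvation around the metallic
cup, head and stem produce dark and bright streaks that corrupt CT numbers
in exactly the periprosthetic bone a radiologist needs to assess. Two
mitigation strategies dominate clinical practice: projection-domain metal
artifact reduction software (here called MAR; the emulated algorithm class
is orthopedic MAR, O-MAR), and high-energy virtual monochromatic images
(VMI, here 130 keV) synthesized from dual-energy acquisitions. phantoMAR
provides a fully simulated, seeded version of the standard phantom
experiment used to quantify how much each strategy — alone and combined —
reduces artifacts: a water-filled PMMA body carrying 18 bone-density
pellets, imaged without prostheses (reference), with a unilateral
prosthesis, and with bilateral prostheses, each reconstructed conventionally
and as 130 keV VMI, with and without MAR.

The package implements the full chain — phantom rasterization,
parallel-beam projection, artifact corruption, filtered back projection
(FBP), MAR and VMI emulation, standardized ROI measurement, pellet
categorization, the normalized artifact metric, relative MAR percentages,
and exact paired Wilcoxon tests — so the whole analysis runs from a single
seed with no external data.

## Quantities measured

For every pellet and condition a standardized circular ROI yields the mean
CT number (HU), the noise (standard deviation inside the ROI), the
signal-to-noise ratio SNR = mean/noise, and the contrast-to-noise ratio
CNR = (pellet − background) / ((pellet noise + background noise)/2), with
one background ROI in artifact-free water. CNR is kept signed: severely
affected pellets can fall below the water background, and the sign carries
that information.

Artifact burden is expressed per pellet as the normalized deviation from
the no-prosthesis reference,

$$\Delta V = \left|1 - \frac{V_\text{with prostheses}}{V_\text{no prostheses}}\right|,$$

where $V$ is any of the four metrics and the reference is the all-pellet
mean of the no-prosthesis scan of the same reconstruction family
(normalization makes conventional and VMI comparable despite their
different HU scales: 130 keV pellets sit near 150 HU, conventional near
248 HU). Reconstructions are compared through the relative metal artifact
reduction

$$\text{relative MAR}(\%) = \left(1 - \frac{\Delta V_\text{reconstruction}}
{\Delta V_\text{standard}}\right)\times 100,$$

computed per metric within the mildly and severely affected pellet
categories; negative values mean aggravation. Pellets are categorized on
the conventional no-MAR image: mean < 0 HU severe, 0–235 HU mild,
≥ 235 HU unaffected (the 235 HU default reproduces the cutoff used with
this phantom; `deriveCutoff()` implements the mean − k·SD rule, floored to
5 HU, for other phantoms). The boundary value 0 HU is assigned to the
milder class so the rule is total. Paired two-sided Wilcoxon signed-rank
tests over the per-pellet $\Delta V$ pairs accompany every table cell; with
at most 18 pairs per cell the exact distribution is always used.

Two aggregation orders are possible for the category percentage and the
choice matters when some pellets have tiny $\Delta V_\text{standard}$: the
default is the ratio of category means (robust), with per-pellet
ratio-then-mean available via `aggregation = "mean_of_ratios"`.

## The simulator

`generateStudy()` emits all 12 condition images. The chain per
configuration and energy is: rasterize → forward-project → corrupt →
(optionally) MAR-inpaint → FBP.

* **Geometry.** 330 mm field of view on a 512×512 grid (0.645 mm pixels),
  a 320×290 mm rounded-rectangle PMMA shell filled with water, 18 pellets
  of 10 mm diameter at 248.4 HU (conventional) / 150.4 HU (130 keV).
  The published phantom places pellets in acetabular (DeLee–Charnley) and
  femoral (Gruen) zones without millimetre coordinates; the packaged layout
  realises those zones as mirrored columns lateral and medial to the stem
  and two acetabular positions, at distances where the artifact response is
  graded and monotone in severity. Positions are config-overridable.
  Prosthesis components are a hemispherical cup (half-annulus, 22–29 mm),
  a 28 mm head and a capsule stem; materials follow the study design
  (unilateral: UHMWPE cup, ZTA head, TiAlV stem; bilateral: UHMWPE/ZTA/
  CoCrMo right, CoCrMo/CoCrMo/TiAlV left) with nominal HU 80 / 10000 /
  8000 / 12000 and water = 0 by definition.

* **Projection.** Ray-driven parallel-beam line integrals of linear
  attenuation, μ = μ_water(1 + HU/1000) with μ_water = 0.0192 mm⁻¹, over
  uniform angles in [0, π) (default 360), detector at half-pixel pitch
  (2× oversampling). Each ray also integrates an attenuation-weighted
  metal path m (mm of HU/10⁴-weighted metal), which defines the metal
  trace and drives the artifact models; weighting makes CoCrMo the worst
  actor, as it is clinically.

* **Beam hardening.** Trace rays are depressed by β·m² (m in cm),
  saturating smoothly toward 85 % of the ray's water-equivalent line
  integral — an unbounded quadratic would push long through-implant rays
  to negative line integrals whose filtered side lobes dominate the image
  with nonphysical ±2000 HU lobes. A Gaussian scatter penumbra
  (σ = 2.5 mm along the detector) spills a fraction of the depression just
  beyond the trace; this tail is precisely the residual that survives
  trace-limited MAR inpainting, and is what leaves conventional-with-MAR
  images imperfect in reality.

* **Photon starvation.** Detector counts are Poisson with mean
  I₀·exp(−p), re-logged with a floor of 0.25 counts; at the default
  I₀ = 6.5×10⁹ per bin the no-prosthesis pellet noise is ≈ 7 HU, matching
  the reference noise scale, while rays through stacked CoCrMo components
  still starve. Flux at or above 10¹⁰ is treated as noiseless; the
  injected ground-truth labels use that limit.

* **FBP.** Ram-Lak filtering with a capped inverse-sinc² "sharp kernel"
  boost that compensates the grid-sampling MTF (the analogue of the sharp
  reconstruction kernels used clinically for prosthesis imaging; without
  it the 15-pixel ROI mean of a 15.5-pixel pellet is biased ≈ 10 HU low by
  edge roll-off), then pixel-driven backprojection.

* **MAR emulation.** Prior-based projection completion, the class of
  algorithm vendor orthopedic MAR belongs to. Stage 1 bridges the
  metal-trace bins of each projection with a smoothing spline fitted to
  the untraced bins (`spar = 0.6`; a straight-line bridge loses the
  curvature of the body's dome-shaped projection profile across wide
  merged bilateral traces and shades the inter-implant region dark by
  hundreds of HU — the known failure mode of plain linear-interpolation
  MAR). Stage 2 reconstructs the bridged data, classifies the image into
  a prior (air stays air, water-like shading is flattened to 0 HU,
  bone-density structure and the PMMA shell are kept), forward-projects
  the prior and replaces the trace bins with its projections — restoring
  the pellet signal that wholesale bridging erases (pellets between
  bilateral implants sit inside the merged traces for most angles and
  would otherwise lose most of their contrast). Both stages depend only
  on untraced data, so the operation is idempotent bit for bit and leaves
  a metal-free sinogram untouched: no-prosthesis images with and without
  MAR are bit-identical, as they are on the scanner. The metal itself is
  not re-inserted into the MAR image. Pure \code{"spline"} and
  \code{"linear"} bridges remain available for comparison.

* **VMI emulation.** The 130 keV branch shares the acquisition seed
  (dual-layer detectors derive VMI from the same acquisition), rasterizes
  its own contrast scale (pellets 150.4 HU, metals at 55 % of their
  conventional HU), is corrupted with β_VMI = 0.1·β (high keV suppresses
  beam hardening) and flux ratio 0.48 (the VMI reference noise sits above
  the conventional one), and receives an additive bright-streak term: on
  the fifth of trace-bearing angles with the widest metal trace — the
  maximal-hardening directions, with bilateral implants the rays through
  both prostheses — the positive part of the trace's excess over its
  inpainting bridge is amplified by γ. After FBP these over-weighted
  directions are the positive streaks seen on high-keV VMI, radiating
  between the implants — exactly where severely affected pellets lie,
  which is how VMI alone aggravates severe artifacts. Because the
  additions live on the trace, MAR inpainting removes them: VMI with MAR
  shows no bright artifacts.

### Default severity and what it reproduces

`defaultSeverity()` is β = 0.6, I₀ = 6.5×10⁹, γ = 1.2. These values were
fixed once so the simulator reproduces the qualitative signature of the
phantom experiment: no-prosthesis pellet statistics near the reference
values (mean ≈ 248 HU, noise ≈ 7 HU conventional; ≈ 150 HU, ≈ 8 HU VMI);
mild artifacts only under a unilateral prosthesis; severe (sub-zero HU)
pellets only between bilateral implants, in numbers (≈ 6–8 of 18) that give
the exact Wilcoxon test room to reach significance as the published
per-category tests did; MAR strictly reducing the streak index; VMI alone
cleaning mild artifacts but aggravating severe ones through bright streaks;
VMI plus MAR strongest overall. They are study conditions, not tuning
knobs, and the parameter-recovery and monotonicity tests run on a grid
around them.

### Ground-truth labels

The generator's injected severity class per pellet-instance is defined by
the noise-free limit of its own chain: the conventional no-MAR image at
infinite flux, measured and categorized exactly like the data. Parameter
recovery then asks that the noisy measurements recover those labels
(≥ 90 % across the severity grid; residual mismatches sit at category
borders by construction).

## Numerical choices

* ROI membership is half-open (pixel centre strictly inside the circle,
  centre-inclusive); ROIs with fewer than 9 pixels are an error.
* ROI noise is the population SD (divide by n); the sample convention is
  available (`sdMode = "sample"`) and differs by < 1 % at ≥ 100 pixels.
* The default ROI diameter is 15 pixels on the 512 reference grid, the
  operational description of the drawn ROI; on coarser simulation grids
  the template switches to its physical 6.75 mm diameter so the ROI stays
  inside the 10 mm pellet.
* Wilcoxon: zeros dropped before ranking (Pratt's method via
  `zeros = "pratt"`), midranks for ties, exact null distribution by
  dynamic programming over doubled midranks up to n = 20, tie-corrected
  normal approximation with continuity correction above.
* Degenerate inputs give flagged results, not errors: all-zero differences
  → p = 1 with `degenerate = TRUE`; zero noise → NA SNR with a warning;
  zero reference or zero standard ΔV → NA with a warning and exclusion.
* Exported measurement CSVs serialize doubles at 17 significant digits so
  the re-analysis mode reproduces simulate-mode tables byte for byte.

## Problem sizes

The validation suite and the acceptance script run the study at a 256×256
matrix with 180 angles (and the severity-grid recovery at 192×192 / 120),
which preserves every qualitative feature of the 512-grid default while
keeping a full multi-condition run in tens of seconds; the 512×512 / 360
default is used when reproducing the reference image-quality table, where
the 15-pixel ROI convention applies. All sizes are arguments, so any run
can be repeated at full scale.

## What the simulator does and does not emulate

It emulates the phenomena the analysis needs — reference-accurate pellet
statistics, severity graded by configuration and material, MAR that
corrects the trace but not the penumbra, VMI that trades beam hardening
for bright streaks and slightly higher noise. It does not model the
polychromatic spectrum or dual-layer detector physics (VMI is emulated,
not decomposed), scatter beyond the penumbra tail, 3-D/helical geometry
(a single coronal slice is simulated), vendor-faithful O-MAR/IMR
(a generic inpainting MAR stands in), or soft tissue. Passing tests
therefore demonstrate that the measurement-and-statistics pipeline is
correct and that the artifact emulation reproduces the study's qualitative
structure — not that the simulator predicts any particular scanner's
absolute numbers.

A packaged synthetic per-pellet table
(`inst/extdata/synthetic_pellet_metrics.csv`, marked synthetic in name and
here) exercises the re-analysis entry point in the layout of a
supplementary per-pellet spreadsheet; its values are hand-designed to
follow the qualitative pattern above and are not measurements.

## Known limitations

Pellet coordinates within the radiographic zones are a package choice, and
near-field filter lobes make per-pellet artifact amplitude sensitive to
position: the packaged layout was chosen where the response is graded and
monotone, and custom layouts should be checked with `streakIndex()` before
being trusted. MAR here is idealized inside the trace (vendor algorithms
are typically worse there and better outside). The bright-streak term is
angular-subset-based, a visual and statistical stand-in rather than a
physical model of VMI extrapolation error. Relative-MAR percentages from
the simulator are therefore comparable to published phantom values in sign
and ordering, not digit by digit. One known divergence: in the simulation
the mild-category CT-value cells of VMI without MAR come out negative,
because several mildly affected pellets of the mirrored layout lie on the
same maximal-hardening corridors as the severe ones and receive the same
bright streaks; published phantom data show clear mild improvement there.
The severe-category pattern — VMI alone aggravating what conventional MAR
fixes, VMI plus MAR matching it — is reproduced.
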