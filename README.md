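# phantoMAR

Quantitative analysis of metal artifact reduction (MAR) in CT imaging of
total hip arthroplasty (THA), as performed in phantom studies: a
water-filled PMMA body carries 18 bone-density pellets in the acetabular
(DeLee–Charnley) and femoral (Gruen) zones; the phantom is imaged without
prostheses (reference), with a unilateral and with bilateral hip
prostheses; every acquisition is reconstructed conventionally and as
130 keV virtual monochromatic imaging (VMI), each with and without
orthopedic MAR. phantoMAR simulates the whole experiment from a single
seed — no scanner or data download required — and implements the full
quantitative analysis so it can equally re-analyse per-pellet measurements
from a real phantom.

The core quantities: per pellet and condition, a standardized 15-pixel
circular ROI yields mean CT number, noise (SD), SNR = mean/noise and
CNR = (pellet − background) / mean of the two noises. Each pellet's
artifact burden is the normalized deviation from the no-prosthesis
reference,

    ΔV = | 1 − V_with_prostheses / V_no_prostheses |,

and reconstructions are compared per metric within mildly (0–235 HU) and
severely (< 0 HU) affected pellet categories through

    relative MAR (%) = (1 − ΔV_reconstruction / ΔV_standard) × 100,

negative values meaning aggravation, with exact paired Wilcoxon
signed-rank tests over the per-pellet ΔV pairs.

The simulator is a compact CT physics chain: analytic phantom
rasterization, parallel-beam projection (Rcpp), beam hardening with a
scatter penumbra, Poisson photon starvation, Ram-Lak FBP with a sharp
kernel, prior-based MAR inpainting, and a VMI emulation with
residual-proportional bright streaks. See the methods vignette
(`vignettes/phantom-mar-methods.Rmd`) for the model, its assumptions and
its limitations.

## Worked example

```r
library(phantoMAR)

# simulate the full 12-condition study (validation grid size)
study <- generateStudy(seed = 1L, matrixSize = 256L, nAngles = 180L)
records <- measureStudy(study)
refs <- computeReferenceValues(records)
refs
#>   reconstruction  mean_hu       cnr      snr    noise
#> 1   conventional 245.2380 11.291773 17.22427 14.66879
#> 2         vmi130 148.7136  6.763106 10.82241 14.20637

tabulateCategories(records)
#>       config unaffected mild severe
#> 1  bilateral          0   12      6
#> 2 unilateral         13    5      0

res <- compareAll(records, refs)
subset(res$table3, metric == "mean_hu")
#>       reconstruction  metric category  n relative_mar_pct     p_value
#> 1  conventional_omar mean_hu     mild 17         16.58290 0.243499756
#> 2  conventional_omar mean_hu   severe  6         51.95883 0.031250000
#> 9      vmi130_noomar mean_hu     mild 17       -146.35250 0.009338379
#> 10     vmi130_noomar mean_hu   severe  6        -32.52107 0.687500000
#> 17       vmi130_omar mean_hu     mild 17         22.36296 0.056884766
#> 18       vmi130_omar mean_hu   severe  6         65.02326 0.031250000

subset(res$table4, metric == "mean_hu" & category == "severe")
#>    reconstruction  metric category n relative_mar_pct p_value
#> 2   vmi130_noomar mean_hu   severe 6       -175.84900 0.15625
#> 10    vmi130_omar mean_hu   severe 6         27.19424 0.43750
```

The no-prosthesis references recover the pellet's nominal 248.4 HU
(conventional) and 150.4 HU (130 keV) to within the reconstruction's
partial-volume tolerance at this grid size; severe pellets appear only
with bilateral prostheses; conventional MAR reduces severe CT-value
artifacts by about half (exact Wilcoxon p = 0.031 over 6 pellet pairs);
and in the comparison against conventional MAR (`res$table4`), VMI alone
aggravates severe CT-value artifacts (negative percentage) while VMI
combined with MAR does not — the study's headline pattern.

Re-analysis mode takes any per-pellet measurement table in long format
(`pellet_id, config, reconstruction, omar, mean_hu, noise, snr, cnr`):

```r
res <- reanalyzeMeasurements("measurements.csv",
                             references = referenceValues())
```

A thin CLI covering simulate / measure / reanalyze is installed at
`system.file("scripts", "phantomar", package = "phantoMAR")`.

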