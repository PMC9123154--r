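# cmfseg

Automatic, unsupervised segmentation of contrast-enhancing breast lesions
from dynamic contrast-enhanced (DCE) MRI volume pairs.

DCE-MRI acquires a pre-contrast volume and post-contrast volumes after
contrast injection; lesions enhance preferentially, so the registered
subtraction `I_sub = max(I_reg − I_pre, 0)` highlights them against a
suppressed background. `cmfseg` turns that subtraction into a lesion mask in
three stages:

1. **Pre-processing** — in-plane affine registration of the post frame onto
   the pre frame (robust MSE metric, bicubic resampling), subtraction,
   phase-preserved denoising, and edge-preserving smoothing (adaptive
   Wiener + bilateral).
2. **Lesion detection** — two-label continuous max-flow (CMF) segmentation
   per slice: the convex dual of
   `min_{u∈[0,1]} ∫(1−u)·Cs + u·Ct + C|∇u|`, solved by an
   augmented-Lagrangian scheme with projected spatial flows. An n-label
   Potts-relaxation solver is included.
3. **Post-processing** — disc dilation (radius 5), largest
   connected-component retention, intersection with the raw mask.

The denoiser decomposes each slice with a log-Gabor wavelet bank, estimates
the Rayleigh background-noise scale from the median response amplitude at
the finest scale (`σ = median(A)/√(2 ln 2)`), soft-shrinks amplitudes
against the threshold `τ = μ_R + c·σ_R` while preserving phase exactly, and
reconstructs from the surviving even-symmetric responses — structure lives
in phase, noise does not.

The package also ships the full evaluation suite (Acc, Se, Sp, P, ER, Vs,
DSC, JC, ROC AUC, PSNR), discrete oracles that validate the CMF solvers
(grid min-cut by Edmonds–Karp, exhaustive Potts enumeration), and a
synthetic DCE-MRI phantom generator (ellipsoidal enhancing lesions, Rician
noise, injected misalignment) so everything is testable end to end without
clinical data.

## Worked example

Generate the default synthetic case (8 × 128 × 128, one ellipsoidal lesion
enhancing by 80 gray levels, Rician noise σ = 8, post frame misaligned by
(2.5, −1.5) px and 0.01 rad) and segment it:

```r
library(cmfseg)

spec <- phantomSpec(seed = 42)
case <- generateCase(spec)          # $pre, $post, $gt + clean references
res  <- segmentCase(case$pre, case$post, gt = case$gt)
res
#> CaseResult:
#>   final mask: BinaryMask: 8 x 128 x 128 (z, y, x), 1520 foreground voxels
#>   MetricsReport:
#>      Acc       Se       Sp        P       ER       Vs      DSC       JC
#>  0.99968  0.97863  0.99993  0.99408  0.00032  0.99217 98.62924 97.29556
#>      AUC
#>  0.99028

invertAffine(res@transform)   # recovered misalignment (true: 2.5, -1.5, 0.01)
#> AffineTransform2D: tx=2.469 ty=-1.716 theta=0.002181 rad k=0 sx=1 sy=1
```

The Dice coefficient (DSC, % overlap with the known lesion), Jaccard index
(JC), sensitivity/specificity and AUC are computed against the generator's
ground-truth mask; the recovered transform shows the registration undoing
the injected patient shift to within a quarter pixel in translation under
this noise level. `writeVolume(res@mask,
"mask.nii.gz")` exports the mask; intermediate volumes live in
`res@intermediates`.

A thin command-line launcher covers the same workflow from a shell:

```sh
Rscript inst/scripts/cmfseg phantom --seed 42 --out-dir case/
Rscript inst/scripts/cmfseg segment --pre case/pre.nii.gz \
    --post case/post.nii.gz --gt case/gt.nii.gz --out out/
Rscript inst/scripts/cmfseg evaluate --seg out/mask.nii.gz \
    --gt case/gt.nii.gz --report out/metrics.csv
```

Configuration is a single YAML file mirroring `defaultPipelineConfig()`,
with any key overridable as `--set cmf.lambda_tv=20`.

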