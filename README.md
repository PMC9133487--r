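# visoximetry

Oxygen saturation (sO₂) of individual parafoveal retinal vessels from
visible-light optical coherence tomography (VIS-OCT), as a tested,
reproducible R pipeline. It is written for researchers in retinal imaging
who want to validate, extend, or re-run the processing chain behind
baseline parafoveal oximetry — from raw spectral interferograms all the way
to per-vessel sO₂ and the cohort-level statistical tables — without access
to patient scans: a synthetic phantom generator with complete ground truth
stands in for the instrument.

## The method

Light returning from a vessel's posterior wall has made a double pass
through the blood column, so its spectrum carries a Beer–Lambert imprint of
the hemoglobin mix:

    I(λ | sO₂, z) = I₀(λ) R₀ · A λ^(−α) · exp(−[sO₂ μ_HbO₂(λ) + (1 − sO₂) μ_Hb(λ)] z)

with `A λ^(−α)` the smooth vessel-wall scattering spectrum,
`μ = μ_a + W μ_s` (W = 0.2) the effective attenuation per hemoglobin
species, and `z` the optical path through blood (round trip through the
lumen). The pipeline:

1. reconstructs a full-band volume (DC removal, FFT over wavenumber) and
   11 Gaussian-windowed spectral sub-bands (short-time Fourier transform),
   giving the 4-D data I(x, y, z, λ);
2. segments the RPE (blur + per-A-line argmax, iterative third-order
   polynomial fitting with a mean ± 1.8 SD outlier rule, COV-based
   rejection of failed B-scans), flattens the retina, and finds the ILM;
3. builds the en-face projection, masks vessel shadows with an adaptive
   threshold, and — per vessel ROI — averages ILM-aligned A-lines, locates
   the vessel bottom as the second reflective peak, extracts the spectrum
   in a [bottom − 5, bottom + 10) window, normalizes it by the non-vascular
   RNFL spectrum, and inverts the model by bounded least squares in log
   space;
4. quantifies vessel topography (centerline length, area, axial diameter,
   min/max distance to the fovea) and reproduces the study's statistics
   (Pearson r with t-transform p-values, pooled unpaired t-tests, per-eye
   and per-segment summary tables).

See the methods vignette (`vignettes/oximetry-methods.Rmd`) for the model
assumptions, phantom design, and every numerical convention.

## Worked example

Invert a noiseless synthetic spectrum generated at the arterial per-eye
mean saturation of the baseline cohort (92.1 vol%):

```r
library(visoximetry)

tab    <- extinction_table()
lambda <- seq(520, 600, length.out = 11)
spec   <- model_spectrum(so2 = 0.921, A_refl = 1, alpha = 1,
                         z_path_mm = 0.05, table = tab, lambda_nm = lambda)
fit_so2(spec, lambda, z_path_mm = 0.05, table = tab)
#> oximetry fit: sO2 = 92.1 vol% (A = 1, alpha = 1.00, resid = 2.02e-07)
```

The fit recovers the generating saturation (92.1 vol%), amplitude, and
scattering exponent; the residual is at numerical noise level.

Run the whole pipeline on a phantom containing one 24.8 µm arteriole
(16 depth pixels at a 1.55 µm axial pitch):

```r
nB <- 32; nA <- 64
vessel <- list(path = cbind(seq(6, nB - 5), nA / 2), diameter_um = 24.8,
               so2 = 0.921, label = "artery", depth_offset_px = 40)
cfg <- phantom_config(n_bscans = nB, n_alines = nA, n_depth = 512,
                      n_spectral = 1024, fov_mm = nA * 0.02,
                      depth_pitch_um = 1.55,
                      rpe = list(center_px = 380, bow_px = 4),
                      retina_px = 200, vessel_specs = list(vessel), seed = 1)
res <- run_pipeline(cfg, out_dir = NULL)
res$segments[, c("label", "L_mm", "D_um", "so2_volpct", "true_so2_volpct")]
#>    label L_mm D_um so2_volpct true_so2_volpct
#> 1 artery 0.42 24.8   91.57706            92.1
```

The axial diameter is recovered exactly (24.8 µm, the cohort's mean
arteriole caliber) and the fitted sO₂ lands within half a vol% of the
buried truth; `out_dir` would additionally receive CSV tables, JSON
sidecars, TIFF images, and a run log.

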