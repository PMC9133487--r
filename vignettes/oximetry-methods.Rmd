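---
title: "Parafoveal VIS-OCT oximetry: models, phantom design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parafoveal VIS-OCT oximetry: models, phantom design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visoximetry)
```

## The measurement problem

Visible-light optical coherence tomography (VIS-OCT) can measure hemoglobin
oxygen saturation (sO~2~) in individual parafoveal vessels of 20-40 µm
caliber because hemoglobin absorbs strongly in the 520-600 nm band and the
depth resolution of OCT isolates the light that has passed through a single
vessel lumen. The quantity of interest per vessel is the spectrum of the
reflex from the vessel *bottom* (posterior wall): light reaching it has made
a double pass through blood, so its spectrum carries a Beer-Lambert imprint
of the blood column,

$$ I(\lambda \mid sO_2, z) \;=\; I_0(\lambda)\, R_0\, A\lambda^{-\alpha}\,
   e^{-\left[ sO_2\,\mu_{HbO_2}(\lambda) + (1 - sO_2)\,\mu_{Hb}(\lambda)
   \right] z}, $$

where $A\lambda^{-\alpha}$ models the smooth scattering spectrum of the
vessel wall, $\mu = \mu_a + W\mu_s$ is the effective attenuation per
hemoglobin species with the scattering contribution scaled by $W = 0.2$, and
$z$ is the optical path through blood. `model_spectrum()` implements this
forward model (with $I_0 R_0$ set to unity because measured spectra are
normalized by a non-vascular reference before fitting, and $\lambda$
normalized by 560 nm so $A$ stays of order one); `fit_so2()` inverts it.

Patient volumes behind the published cohort are not deposited, so the
package is built around a synthetic phantom (`make_phantom()`) that buries
every quantity of interest — layer surfaces, vessel geometry, per-vessel
sO~2~ — in a raw spectral-interferogram volume, and every downstream stage
is validated against that buried truth.

## Pipeline stages

1. **Reconstruction** (`reconstruct_fullband()`): per A-line DC removal,
   FFT over the spectral axis (uniform in wavenumber $k$), magnitude,
   positive-depth half. A dispersion hook exists but defaults to identity;
   phantom fringes are synthesized dispersion-free in linear $k$.
2. **Spectral sub-bands** (`stft_subbands()`): a short-time Fourier
   transform with 11 Gaussian windows swept across the interferogram yields
   the 4-D data $I(x, y, z, \lambda)$. Windows are equally spaced in $k$,
   inset by half a window at the support edges, and normalized to unit sum.
   The window FWHM defaults to 1/8 of the source support (about 50%
   overlap); only the window *count* is fixed by the method, the width is a
   package choice exposed in the interface.
3. **Segmentation** (`segment_layers()`): each B-scan is blurred with a 2-D
   Gaussian (SD 7 px) and the RPE is taken as the per-A-line intensity
   argmax. A third-order polynomial is fitted per B-scan; points whose
   residual falls outside mean ± 1.8 SD are deleted and replaced by the
   fitted value, iterating until no outlier remains. B-scans whose fitted
   curve has an outlying coefficient of variation (same ± 1.8 SD standard
   over the COV trace) are replaced by the nearest previous valid curve.
   The retina is then flattened to a common RPE row and the ILM is the
   largest axial intensity gradient above it (profiles smoothed with
   SD 1 px to stabilize ties).
4. **Vessel mask** (`make_enface()`, `vessel_mask()`): the en-face image
   averages a 20-px band above the RPE; vessels appear as shadows and are
   binarized with a local-mean adaptive threshold, small objects (< 10 px)
   discarded.
5. **Per-vessel oximetry** (`vessel_oximetry()`): A-lines in a vessel ROI
   are aligned to the ILM and averaged; the vessel bottom is the second
   reflective peak below the ILM; the spectrum is averaged over
   [bottom − 5, bottom + 10) rows, normalized by the non-vascular RNFL
   spectrum, and inverted by bounded least squares in log-intensity space
   (sO~2~ ∈ [0, 1], α ∈ [−4, 4], multi-start at sO~2~ = 0.25/0.5/0.75,
   ties broken by residual then by lower sO~2~).
6. **Topography** (`vessel_topography()`): centerline length (longest
   geodesic of the Zhang-Suen skeleton), mask area, *axial* diameter from
   the top/bottom peaks of the averaged A-line, and min/max Euclidean
   distance from the fovea (fovea position supplied, not detected).
7. **Statistics** (`correlation_table()`, `summarize_segments()`): Pearson
   correlations with two-sided t-transform p-values and pooled-variance
   unpaired t-tests (Welch by flag), without multiple-testing correction;
   significance is flagged at p < 0.05.

## What the phantom emulates, and what it does not

Fringes are a DC level plus, per interface $j$,
$I_0(\lambda) R_j(\lambda) \cos(2\pi (z_j - 1) n / N)$ sampled uniformly in
$k$: the ILM (RNFL power-law reflectance), a weak continuous scatter band
above the RPE (the en-face signal carrier), vessel top/bottom interfaces,
and a bright spectrally flat RPE. The vessel-bottom reflectance and the
shadow cast on everything beneath a vessel follow the forward model's
double-pass attenuation through the local lumen chord at the configured
true sO~2~. Corrupt B-scans are replaced by saturated noise; shot noise is
additive Gaussian scaled to the DC level; a seed fixes all randomness.

Deliberate simplifications, and their consequences for what passing tests
show about real data:

* **No speckle, no eye motion, no choroid.** Surface recovery and sO~2~
  accuracy on the phantom are upper bounds for clinical performance; the
  suite validates the *algorithms*, not clinical robustness.
* **Interfaces are sharp.** OCT reflexes arise from refractive-index steps,
  and the reconstruction point-spread function already lends each peak its
  finite width; a coherent multi-row "thick" reflector would imprint a
  spurious carrier-phase modulation on the sub-band spectra, so the
  generator deliberately avoids it.
* **The DC term is spectrally flat**, so per-A-line mean subtraction
  removes it exactly and the source shape appears only in the interference
  terms (as the axial PSF). A real reference-arm spectrum would leave a
  zero-delay artifact that this package does not model.
* **Detection outliers are hyper-reflective RNFL patches** about 14
  A-lines wide (at most one per B-scan, `spike_rate` = expected fraction
  of affected A-lines). Isolated single-A-line spikes would vanish under
  the σ = 7 segmentation blur; patches reproduce the documented failure
  mode in which the RPE argmax jumps to a bright inner retina.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `blur_sigma` | 7 | px | pre-detection B-scan blur |
| `poly_order` | 3 | — | per-B-scan RPE fit |
| `outlier_k` | 1.8 | SD | residual/COV outlier rule |
| `enface_band_px` | 20 | px | en-face band above RPE |
| guard gap | 2 | px | keeps a ±1 px RPE error from leaking the bright RPE row into the en-face band |
| STFT windows | 11 | — | spectral sub-bands |
| window FWHM | support/8 | nm | resolution/contrast trade-off |
| `W` | 0.2 | — | scattering scale in $\mu$ |
| bottom window | [−5, +10) | px | spectrum extraction around the bottom |
| z-path | 2 × lumen depth | mm | round trip through blood |
| α bounds | [−4, 4] | — | scattering exponent |

The extinction table bundled in `inst/extdata/` is a *synthetic* smooth
approximation to the canonical visible-band Hb/HbO~2~ compilations
(anchor molar extinctions splined to 1 nm, converted to whole-blood
µ~a~ at 150 g/L, Mie-like power-law µ~s~). It reproduces the features that
carry oximetric contrast — the HbO~2~ α/β double peak at ~542/576 nm, the
single broad Hb peak at ~555 nm, the large deoxy excess above 590 nm — but
it is not a measured dataset, and absolute sO~2~ values from clinical data
would inherit its approximation error. Forward-inverse recovery, which is
what the tests assert, is independent of that error because both directions
use the same table.

## Numerical choices and conventions

* **Indexing** is 1-based throughout; depth row 1 is the zero-delay line.
  Depth bands are half-open as documented per function.
* **The fit runs in log intensity**, which linearizes the Beer-Lambert
  exponent; for fixed sO~2~ the parameters $(\log A, \alpha)$ are linear
  and are profiled in closed form to initialize each multi-start.
* **Peak detection for the vessel bottom uses the full-band profile**
  (the coherent average over the entire source spectrum), not the mean of
  sub-band magnitudes: sub-bands trade axial resolution for spectral
  resolution, and a 20-30 µm lumen's top/bottom reflexes can merge at
  sub-band resolution. The spectral matrix itself remains sub-band data.
* **SD recomputation**: the ± 1.8 SD statistics are recomputed over current
  inliers at every refinement iteration; a residual spread at
  floating-point noise level terminates the loop (a perfect fit has no
  outliers). COV detection is repeated on the updated trace until no new
  outlier appears, so grossly failed segmentations cannot mask each other;
  replacement of a flagged first B-scan falls back to the nearest
  *following* valid curve, where "previous" is undefined.
* **Axial pitch in test phantoms is 1.55 µm/px** (24.8 µm lumen = 16 px):
  with the prescribed [−5, +10) extraction window, the window then stays
  inside the lumen shadow; at a coarser 3.1 µm pitch the window's upper
  rows graze the unattenuated top reflex and bias the fit. The phantom
  default (3 µm/px) is documented for generic use; oximetry fixtures pass
  the finer pitch explicitly.
* **Lateral field of view in vessel fixtures** is chosen so a 20-40 µm
  vessel spans at least one lateral pixel (e.g. 10-20 µm/px over a
  parafoveal sub-field); at the full 5 mm FOV across 128 A-lines a
  parafoveal vessel is narrower than a pixel.
* **Residual phantom-level sO~2~ bias** of a few vol % (well under the
  cohort's between-eye SD) remains from edge-window truncation and
  top/bottom reflex cross-talk; the model-level inversion is exact to
  better than 0.1 vol %, as the acceptance checks assert.

## Statistical reference values

The per-eye correlation table of the published 16-eye baseline cohort is
embedded (`baseline_cohort_correlations()`) and used as a validation suite
for the t-transform: 18 of the 21 printed (r, p) pairs are reproduced within
± 0.01 at n = 16; the three refraction-cylinder pairs are reproduced only at
n = 13, implying three eyes lacked a cylinder measurement, and the embedded
table records that inferred per-row n. `check_printed_correlations()`
recomputes every p from its r and n.

## Problem sizes

Desk-scale grids keep the full suite fast while preserving every failure
mode the stages must handle: segmentation phantoms use 48 × 128 A-lines at
256 depth px; oximetry phantoms 32 × 64 at 512 depth px from 1024 spectral
samples; the end-to-end determinism check runs a 64 × 128 raster twice. The
clinical 512 × 256 raster remains reachable through `phantom_config()`.

## Known limitations

* ROI-averaged diameters of laterally resolved vessels mix off-center
  chords and sit slightly below the centerline lumen; the acceptance
  fixture uses a centerline ROI, as manual ROI selection would.
* The COV replacement rule can benignly replace a few healthy B-scans when
  the COV trace varies smoothly (bowed retina); replacements copy a
  neighboring curve and move surfaces by well under a pixel.
* Artery/vein labels and the fovea position are inputs (phantom truth or
  annotation), matching the manual practice of the clinical protocol; no
  automatic classification is attempted.
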