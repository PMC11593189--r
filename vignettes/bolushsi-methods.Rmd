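---
title: "Models and methods behind bolushsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bolushsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bolushsi)
```

# The problem

During oral processing a bread bolus is progressively wetted by saliva,
its starch is hydrolyzed to reducing sugars, and its mechanical
resistance collapses. Near-infrared hyperspectral imaging can track all
three because water, carbohydrates and fat have distinct overtone
absorptions in the 899–1748 nm window: O–H second overtone near 960 nm,
C–H second overtone near 1200 nm, and the strong O–H first overtone near
1450 nm. `bolushsi` turns the standard analysis of such experiments —
reflectance calibration, spectral pretreatment, latent-variable
regression, pixel-wise mapping, texture statistics, rank correlation —
into a tested, seeded pipeline, and supplies a synthetic scene generator
so every stage is verifiable without instrument data.

# Reflectance calibration and conventions

Raw intensity cubes are corrected with the two-point formula
$R = (I - B)/(W - B)$ using dark-current ($B$) and white-reference ($W$)
frames. Conventions the literature usually leaves implicit, fixed here:

* **Coordinates** are 0-based and row-major; an ROI is half-open
  `[start, start + size)` and a centered ROI starts at
  `floor((dim - size)/2)`. Oversized ROIs are errors, never silently
  shrunk.
* **References** may be full frames, push-broom line references
  (`1 x cols x bands`, broadcast over rows), or per-band vectors. Any
  non-positive $W - B$ aborts with the offending band indices.
* **Clipping**: reflectance is clipped to $[0, 1.05]$ — noise can push
  bright pixels slightly above 1 — and the number of clipped voxels is
  reported in an attribute, never silently discarded.
* **nm → band lookup** uses the nearest band, ties to the lower index.

# Spectral pretreatments

Three alternatives are supported, mirroring the common NIR workflow:
Savitzky–Golay smoothing (SG), Gaussian filtering (GF) and normalization
(N). They are *alternatives*, not a chain: each candidate model uses
exactly one, and the choice is recorded in the model's provenance.

Since typical instrument-software defaults are unrecoverable from most
papers, the defaults here are standard NIR choices, all configurable:
SG window 11 bands / polynomial order 2; GF $\sigma = 2$ bands truncated
at $4\sigma$ and renormalized to sum 1; normalization in unit-vector mode
(min–max and SNV available). All filters use mirror (reflect) boundary
padding with the edge sample not duplicated; SG therefore reproduces
polynomials of degree ≤ order exactly in the interior, and both filters
are exactly linear — both properties are tested.

# Regression models

PLSR uses univariate-response NIPALS (one model per analyte) on
mean-centered $X$ and $y$, without unit-variance scaling of $X$ — the
usual convention for spectra, where the band-to-band variance structure
is informative. Per component: $w = X^\top y / \|X^\top y\|$, $t = Xw$,
$p = X^\top t/(t^\top t)$, $q = y^\top t/(t^\top t)$, rank-one deflation
$X \leftarrow X - t p^\top$; the per-band coefficient vector is
$b = W(P^\top W)^{-1} q$. A component with numerically zero score norm
truncates the model with a warning. PCR takes the SVD of centered $X$ and
regresses $y$ on the leading scores. Both reduce to ordinary least
squares at full rank, and PLSR's calibration residual never exceeds PCR's
at equal component count — both are tested against a normal-equations
oracle.

Model assessment follows the calibration / cross-validation / prediction
triplet (RC²/RMSEC, RCV²/RMSECV, RP²/RMSEP). Choices where the field's
papers are typically silent:

* **Split**: Kennard–Stone max–min selection on the preprocessed spectra
  (seeded random split available), 3:1 calibration:prediction by a floor
  rule.
* **Cross-validation**: seeded 10-fold with per-fold re-centering;
  leave-one-out is the `folds = n` special case.
* **Component count**: the smallest $k$ whose RMSECV is within 2% of the
  global minimum over $1..k_{max}$ ($k_{max} = 15$ by default) — a
  parsimony rule that avoids the noise-chasing tail of the RMSECV curve.
* **Ties** everywhere resolve to the lowest index, so runs are
  deterministic.

# The synthetic world

The generator emulates a chewing experiment: two formulations (plain
wheat `B0`, fiber factor 0; 50% whole-wheat `B50`, fiber factor 0.5),
chew times 0/6/12/18 s, 8 panelists × 3 replicates, 899–1748 nm with 512
bands (64×64-pixel scenes by default, for test speed; all sizes are
configurable).

**Label trajectories.** Only endpoint values are available from the
motivating experiments, so each label follows a saturating exponential
anchored *exactly* at its endpoints, linear in the fiber factor between
the two formulations: MC (mass fraction) 0.4228 → 0.5510 for B0 and
0.3433 → 0.4724 for B50 (time constant 7 s); chewiness 29.16 → 2.00 N
(B0) and 53.36 → 2.44 N (B50), converging late (time constant 5 s).
Reducing sugars have no published values; 20 → 45 mg/g (B0) and
15 → 32 mg/g (B50) were chosen once as realistic DNS-assay magnitudes
and not revisited. Noise is multiplicative lognormal: a per-panelist
factor with CV 5% plus half-sized replicate scatter, mean 1 so design-
cell means stay on schedule. With noise off all trajectories are strictly
monotone — a tested ordering invariant.

**Spatial fields.** Each analyte's concentration field is a smoothed
Gaussian random field (correlation length 8 px), standardized, scaled to
a scheduled coefficient of variation, clipped at zero (an error if
clipping removes >10% of mass) and rescaled so the scene mean matches the
label exactly through an invertible linear map (water ↔ MC, sugar ↔
RSs/100, fiber ↔ chewiness/100; fat constant at 0.05). The heterogeneity
schedule encodes the qualitative chewing story: MC and chewiness CV rise
to a peak near 6 s (saliva wets the rim first) then relax as mixing
homogenizes the bolus; the RSs CV decays monotonically. The prose of the
motivating study is ambiguous on the RSs direction; the monotone-decay
reading was fixed at design time.

**Optics.** Per pixel, absorbance is $A(\lambda) = \sum_k c_k
\varepsilon_k(\lambda)$ over Gaussian absorption bands at the assignments
above, and reflectance is the Beer–Lambert surrogate $R = e^{-A} \in
(0, 1]$. No radiative-transfer (Kubelka–Munk) realism is attempted: the
point is a smooth, nearly-linear, *invertible* forward model, so that
linear chemometrics can recover the labels and the black/white step can
be validated exactly — raw intensity is re-encoded as
$I = B + R\,(W - B) + \mathcal{N}(0, \sigma)$ with constant reference
levels (0.08/0.92) and detector noise $\sigma = 0.005$ by default, so
calibration inverts the generator to machine precision when $\sigma = 0$.

**What the generator does not emulate** — and therefore what a green
test does *not* establish: scattering and particle-size effects, specular
highlights, non-flat bolus geometry and shadows, wavelength-dependent
detector gain, saliva chemistry, panelist-specific chewing mechanics.
Model performance numbers on this world are upper bounds, not forecasts
of instrument performance.

# Distribution maps and uniformity

A trained model applied pixel-wise (preprocessing included) yields a
concentration map; background pixels are `NA` and the finite-pixel count
always equals the mask popcount. Rendering is a linear blue→red lookup
clamped at a display range shared per analyte — the moving parts of the
comparison are the maps, not the color bars. The shared range is the
pooled 1st–99th percentile span, so single extreme pixels cannot stretch
the scale.

Uniformity is quantified by GLCM contrast
$\sum_i \sum_j (i-j)^2 P(i,j)$ with 64 gray levels, distance 1, the four
offsets (0°, 45°, 90°, 135°), symmetric normalized matrices, and the
direction mean reported. One subtlety found during design: if each map is
quantized over its *own* min–max range, contrast is exactly invariant to
scaling the field amplitude — the statistic would be blind to how uneven
a map is in absolute terms, and the expected monotone relationship
between field heterogeneity and contrast vanishes. The default
`quantize_map()` keeps the conventional per-map range, but
`map_contrast(range =)` accepts a fixed range, and the pipeline
quantizes on the per-analyte shared display range (the same convention
as a shared color bar). The uniformity tests do likewise.

**Pixel-level identifiability.** A model trained on per-bolus mean
spectra learns to predict along the *between-sample* label manifold. In
a noise-free design all three labels are functions of chew time alone,
so their spectral directions are collinear and the fat direction never
varies between samples at all; such a model cannot apportion pixel-level
variation correctly (per-pixel R² against the true field ~0.3–0.7), even
though the pixel-wise application itself is exact (per-pixel agreement
with scalar prediction ≤ 1e-10, tested). This is a genuine property of
calibration transfer in HSI, not an implementation artifact: pixel-level
validation therefore uses models trained on pixel spectra against the
generator's ground-truth fields, which recover held-out fields at
R² > 0.999. Published distribution maps made with sample-level models
should be read as semi-quantitative in exactly this sense.

**Measurement support.** Labels are defined on the whole scene (as a
wet-lab assay consumes the whole bolus), so quantitative recovery tests
use an ROI covering the scene. A smaller ROI adds a field-subsampling
error — the ROI mean of a correlated random field differs from the scene
mean — which lowered the noise-free MC prediction R² from 1.000 to
≈ 0.987 in a half-scene configuration. That mismatch is a realistic
feature of partial-ROI protocols, but it is a property of the sampling
design, not of the estimator under test.

# Wet-lab arithmetic

The oven-drying moisture formula is implemented as printed in the
motivating literature, $(m_1 - m_2)/m_2$ (dry basis), although the
accompanying prose describes a wet-basis quantity; both conventions are
available and every result is tagged with its basis, so the discrepancy
is surfaced rather than silently resolved. The DNS reducing-sugar assay
is a positive-slope OLS standard curve with its inversion; a
non-increasing curve is treated as an invalid assay.

Spearman correlations use mid-ranks (average ranks for ties) and the
t-approximation for two-sided p-values, appropriate at the panel sizes
involved; for n ≤ 8 an exact permutation p-value is enumerated instead.
Constant variables produce flagged cells, never silent `NA`s.

# Determinism and seeds

A single global seed fans out to per-stage seeds through a documented
hash of the stage name, so the sample table, every scene, fold
assignments and splits are independently reproducible; RNG state is
save/restored around every draw so library calls never perturb user RNG.
Two pipeline runs with the same config produce byte-identical report
hashes (tested), and map PNGs are byte-deterministic on the cairo
device.

# Known limitations

* The optical model is a surrogate; absolute RMSEP values on synthetic
  data do not transfer to instruments.
* Chewiness is treated as a label carried by a structural "fiber/matrix"
  field; real chewiness is a bulk rheological property without a single
  spectral carrier, which is one reason real-data R² plateaus well below
  the synthetic ceiling.
* No wavelength selection (CARS/SPA) or nonlinear models — full-spectrum
  linear chemometrics only, by scope.
* The ENVI reader supports the common interleaves, byte orders and
  numeric types but not tiled or compressed variants.
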