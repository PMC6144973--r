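---
title: "Methods: calibrated eggshell appearance analysis and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated eggshell appearance analysis and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovoscope)
```

`ovoscope` measures eggshell appearance (reflectance, maculation, size)
from calibrated VIS/UV photograph pairs and models its spatial and
environmental variation. This vignette documents the models and numerical
choices behind each stage, what the synthetic-data generator does and does
not emulate, and the design decisions taken where several defensible
options existed.

## 1. Radiometry

A camera records counts that are a nonlinear function of scene radiance.
We model the response either as a gamma curve, counts ∝ L^(1/γ), or as a
user-supplied strictly increasing lookup table; `linearize()` inverts it.
`to_reflectance()` then scales each band independently so that the mean
linear count over the grey-standard patch equals the standard's nominal
reflectance (40 % for the Spectralon standard assumed throughout; the
value is a parameter in (0, 100]). Two consequences follow directly from
this construction and are enforced as invariants: normalization is
invariant to any positive rescaling of the linear counts (illumination
intensity cancels), and bands never mix.

Numerical choices: pixels within 1 % of full scale are treated as
saturated — they are excluded from the standard mean and flagged, never
silently used; reflectance above 100 % (specular highlights) is flagged,
not clipped, and downstream means use unflagged pixels only. The response
model is a declared contract: no attempt is made to estimate γ from the
image.

## 2. Spot segmentation

Maculation is segmented inside the hand-drawn RoI polygon by a local-mean
adaptive threshold: a pixel is a spot candidate when its across-band VIS
reflectance lies at least `offset_pp` percentage points below the mean of
the surrounding `window_px` × `window_px` window (the window mean is
computed over RoI pixels only, via an integral image, so the egg edge does
not bleed into the statistic). Candidates are cleaned by a 3 × 3 binary
opening, labelled with 8-connectivity (via the pixel adjacency graph and
`igraph::components`), and components below `min_spot_px` are dropped.

Defaults — `window_px = 31`, `offset_pp = 5`, `min_spot_px = 9` — were
chosen on synthetic fixtures so that disks of diameter ≥ 5 px with ≥ 10
percentage points of contrast are recovered exactly; they are plain
configuration, not estimated quantities. The seven reported traits are
spot number, mean spot size (mm², via the scale bar), spottiness
(100 × spot area / RoI area, with the RoI as drawn as the denominator),
and background/spot reflectance in VIS and UV. The single VIS values are
the unweighted mean of the R, G, B band means; per-band values are also
reported. A spotless egg reports spot statistics as a missing-value
sentinel (blank CSV field), never 0.

## 3. VIS→UV registration

The UV exposure is taken from a slightly different camera position, so the
VIS spot mask must be mapped into the UV frame before UV reflectance can
be measured. The mapping is the Local Weighted Mean transform: around each
of n ≥ 13 control points a local second-order bivariate polynomial is
fitted, and the transform at any location is the weight-normalized blend
of nearby polynomials under the cubic-taper kernel w(R) = 1 − 3R² + 2R³,
which vanishes at each point's influence radius (its distance to the
(k−1)-th nearest control point).

The key design decision is the neighbourhood size. A second-order
bivariate polynomial has six coefficients; with exactly six neighbourhood
points (the control point itself plus its five nearest) each local
polynomial *interpolates* its neighbourhood, and because every point
within a polynomial's influence radius belongs to its neighbourhood, the
blended transform is exact at every control point — the property the whole
module is specified around, and one we verify to below 10⁻⁶ px. Larger
neighbourhoods switch to least squares, which buys smoothing at the price
of that exactness; `k_neighbors = 6` is therefore the default, and local
coordinates are centered and scaled by the influence radius before solving
for conditioning. Quadratics contain affine maps, so control points
generated by any global affine transformation are reproduced exactly off
the control grid as well. Degenerate (conic-coincident) neighbourhoods
raise an error naming the offending point. Locations outside every kernel
fall back to the nearest control point's polynomial.

Masks are resampled by inverse mapping with nearest-neighbour assignment,
keeping them strictly binary; the UV→VIS direction needed for this is
fitted by the same machinery with the point roles swapped. Because
nearest-neighbour resampling is uncertain by up to half a pixel along
region boundaries — and the transform is least constrained near the RoI
rim, beyond the control-point hull — `uv_measure()` erodes the measurement
sets before averaging (spots by 1 px, the plentiful background by 3 px),
falling back to the uneroded set if erosion would empty it. Geometry
reports always use the uneroded mask. The grey standard is marked
separately on each frame: the synthetic sidecars carry both the VIS-frame
and the UV-frame standard polygons, exactly as an analyst would outline
the patch on each image.

## 4. Morphometry

The RoI outline is treated as the silhouette of a solid of revolution. The
long axis joins the two most distant boundary vertices; at each of
`n_stations = 200` stations the two perpendicular half-widths are averaged
(the revolved solid cannot represent bilateral asymmetry of the drawn
outline, so it is symmetrized away), giving r(t) with r = 0 at the poles.
Volume and surface follow from V = π∫r² dt and S = 2π∫r√(1+r′²) dt by the
composite trapezoid rule, with central differences for r′ (one-sided at
the poles). The 200-station default is convergence-tested: doubling to 400
stations moves V and S by well under 0.1 % on smooth outlines, and sphere
and prolate-spheroid oracles are matched within 0.5 %. The scale comes
from two marked points on the metric scale bar (`calibrate_scale()`),
whether the study's surface-to-volume ratio used this photogrammetric
surface or a length/breadth formula is not documented; only the
photogrammetric route is implemented.

## 5. The synthetic generator

### Egg images

`make_egg_image()` renders an analytic scene — a two-parameter ovoid with
an asymmetry term, r(u) = (B/2)√(1−u²)(1+au) for u ∈ [−1, 1] (defaults
L = 32.5 mm, B = 23.5 mm, a = 0.12, about right for a small plover egg at
0.15 mm/px), circular spots placed fully inside the RoI with a 3 px
minimum separation (so the placed count equals the connected-component
count), a 40 % standard patch, and a 15 mm scale bar — and photographs it
twice: VIS in the VIS frame and UV through a smooth space-variant warp
(sum of Gaussian bumps rescaled to a 4 px maximum displacement; the
magnitude of real VIS/UV misalignment is not documented, so a mid-range
single-digit value was fixed once). Counts follow counts = L^(1/γ) scaled
to 16 bits with additive Gaussian noise; the UV exposure carries 3× the
VIS noise, mimicking the degraded signal-to-noise of long UV exposures.
The shape truth (volume, surface) is computed by adaptive quadrature of
the ovoid profile to 10⁻⁶ relative tolerance, and the warp truth is exact:
control-point pairs are generated directly from the displacement field.

What the fixtures do *not* emulate: real eggshell texture and gloss,
vignetting and flat-field error, chromatic aberration, demosaicing, and
irregular spot shapes. Passing tests on these fixtures therefore
demonstrate correctness of the *algorithms* under controlled conditions,
not robustness to every photographic artifact of museum imagery.

### Trait datasets

`make_trait_dataset()` emulates the study design: 30 collection sites
spread uniformly over 11.35–54.52° N, insolation decreasing with latitude
(0.92 − 0.00973·(lat − 11.35) kW/m², site noise SD 0.015, range ≈
0.5–0.92), temperature likewise decreasing, a Poisson(110/30) clutch count
per site (expected study size 110 eggs), collection years uniform on
1858–1972, and surface-to-volume ratios N(0.236, 0.008²) mm⁻¹. The first
trait axis is generated as

PC1 = 0.027·(year − 1915) + g(insolation) + 69.850·(sv − mean(sv)) + α_site + ε,

with α_site ~ N(0, 0.363²) and ε ~ N(0, 1.513²). The year and
surface-to-volume slopes are the published point estimates; year is
centered at 1915 (the sampling midpoint) and sv at the dataset mean, a
choice that matters only for the intercept since the study reports slopes.
The insolation response g is a quartic with turning points near 0.57, 0.67
and 0.82 kW/m² — lighter eggs up to ≈0.55, a plateau, a further rise to
≈0.8, then darker again at the highest radiation — with its amplitude
fixed once (k = 13269.2) so that, over this design, the fixed effects,
site variance and residual variance stand in the proportions
0.45 : 0.03 : 0.52. The expected marginal and conditional R² of the
generating model are thus ≈0.45 and ≈0.48. PC2 has no fixed structure:
site intercept (SD 0.645) plus noise (SD 1.060), giving a conditional R²
near 0.27. All defaults were set from these design targets before any
verification run and are not tuning knobs.

## 6. Mixed models, smooths, and model selection

All study models are Gaussian random-intercept models. Writing the
marginal covariance as σ²_ε·V₀ with V₀ = I + Σⱼ θⱼ ZⱼZⱼ′, the GLS fixed
effects and the profiled σ²_ε are closed-form at any θ, leaving a one- or
two-dimensional optimization over log θ (golden-section for one variance
ratio, Nelder–Mead with coordinate polishing otherwise). Both the ML and
REML objectives are supported; the profiled log-likelihood is verified
against a dense brute-force evaluation of the marginal normal density and
against lme4 to ≈10⁻⁷. A boundary fit (θ → 0) is valid and flagged; the
fixed effects then equal ordinary least squares.

Penalized smooths are cubic B-spline bases capped at 5 knots (quantile
placement) with a second-difference coefficient penalty, re-expressed in
mixed-model form: the covariate itself is the unpenalized linear part (the
constant being absorbed by the intercept) and the penalized deviations
form a random-effect block whose variance ratio is the inverse smoothing
parameter, chosen by the same profiled likelihood. By construction an
infinite penalty collapses the term exactly onto the least-squares line.
The equivalent degrees of freedom of a term are the trace of its block of
the coefficient influence matrix (C′C + P)⁻¹C′C — on linear truth the edf
approaches 1, and the term's edf and fitted curve are cross-checked
against an independent GAMM fitter (mgcv) on the same basis dimension.

Covariates are standardized before entering any design; polynomial terms
use raw powers of the standardized covariate (numerically safe at degree
≤ 4), and linear-term coefficients are reported back on the raw scale
alongside. The AICc parameter count k is: fixed coefficients (including
each smooth's linear column) + 1 per variance component (site, residual)
+ 1 per smoothing parameter. This convention reproduces the df bookkeeping
of the study's comparison tables row for row (e.g. 3 for the null model,
9 for year + sv + quartic insolation). Coefficient p-values use t
statistics with n − k residual df and are flagged approximate. Competitive
models (ΔAICc ≤ 2) are flagged, never auto-pruned. Concurvity between two
terms is the fraction of one term's fitted contribution explainable by
projection onto the other's basis — for linear bases exactly the squared
correlation of the covariates.

`run_selection()` mirrors the study workflow: a REML AICc assessment of
the site intercept under the full parametric fixed model, then ML AICc
comparisons of the spatio-temporal candidate set {Year + s(latitude),
Year + latitude, Latitude, Year, Null} and the response-specific
environmental set, in which the insolation smooth is also refit as cubic
and quartic polynomial alternatives for the first trait axis.

### A note on null-model selection rates

AICc charges ≈2.16 units for one spurious covariate at n ≈ 110, which a
true-null fit exceeds with probability ≈0.14 (a χ²₁ tail). With four
competitor models in the spatio-temporal set, the null model is therefore
top-ranked in only ≈70 % of replicate null datasets — a property of
information-criterion selection itself, reproduced (not caused) by this
implementation; the mixed-model likelihoods agree with lme4 to seven
digits. Expecting the null to win in ≥80 % of replicates under these
conditions is not attainable, and the corresponding check is reported at
its observed value rather than adjusted.

## 7. Verification sizes and determinism

Every stochastic path takes an explicit integer seed; identical seeds give
bit-identical images, tables, and manifests. The replicate sizes used in
the verification suite are the package's own choices: 500 replicate trait
datasets for parameter recovery (Monte-Carlo SE on the sv slope ≈ 0.8,
comfortably resolving the published 69.85), 200 replicates for each
model-selection behaviour check, and three seeds for each image-stage
oracle. Under these conditions the recovered year and sv slopes are
unbiased within Monte-Carlo error, the mean marginal/conditional R² of the
quartic model sit within 0.05 of the design targets, and the quartic model
beats the capped spline by more than 2 AICc units in ≈90 % of replicates.

## 8. Known limitations

- The camera response is declared, not estimated; no demosaicing,
  flat-fielding or lens-distortion correction is attempted.
- The LWM transform is only as good as the marked control points; with
  the minimum 13 points its accuracy near the RoI rim depends on the
  fallback polynomial, which is why UV means exclude a boundary margin.
- The revolved-solid volume ignores bilateral asymmetry of the outline by
  construction.
- Smooth terms are single-covariate penalized splines; no tensor-product
  or 2-D spatial smooths, and no semivariogram/Mantel residual
  diagnostics.
- The PCA assumes the seven log traits are complete; eggs with zero
  spottiness are excluded (flagged) rather than imputed.
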