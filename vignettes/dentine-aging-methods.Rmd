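---
title: "Quantifying dentine aging from multiphoton images: methods and design"
author: "dentineMP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dentine aging from multiphoton images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dentineMP)
```

## The measurement problem

Human dentine is a collagen-rich mineralized tissue traversed by tubules,
each wrapped in a hypermineralized peritubular sheath. With age the
peritubular dentine thickens, the balance between the tissue's two-photon
excited fluorescence (TPEF) and its second harmonic generation (SHG)
shifts, and the internal order of the collagen changes. All three effects
are measurable in co-registered TPEF/SHG image pairs and
polarization-resolved SHG stacks of 180 × 180 µm dentinal fields, and each
correlates linearly with chronological age — which is what makes them
candidates for forensic age estimation.

dentineMP implements the four estimators, the statistical layer that
regresses them on age, and a synthetic-image generator that produces
cohorts with known ground truth so the whole chain can be validated by
parameter recovery.

## The four metrics

**INAG (index of aging).** The normalized channel contrast

$$\mathrm{INAG} = \frac{\tilde I_{SHG} - \tilde I_{TPEF}}
                       {\tilde I_{SHG} + \tilde I_{TPEF}} \in [-1, 1].$$

The tilde is read as the *spatial mean* intensity over unmasked pixels,
the same convention as the SAAID index used for skin photoaging. The
source text does not define the tilde; the channel-mean reading makes
INAG a bijection of the SHG/TPEF mean ratio $r$,
$\mathrm{INAG} = (r-1)/(r+1)$, which `inagSummary()` and
`shgTpefRatio()` satisfy to machine precision and the tests assert.
Whether "the ratio averaged across the image" means a ratio of means or
a mean of pixel ratios is likewise undefined in the source; both are
exposed (`shgTpefRatio(method=)`), the ratio of means being the default
and the convention under which the generator encodes ground truth. The
spatially resolved `inagMap()` smooths each channel with a 1 µm Gaussian
before the pixel-wise quotient (the quotient amplifies noise at dark
pixels) and masks pixels whose summed intensity is at or below 1% of the
joint maximum.

**Peritubule size.** In longitudinal SHG images the peritubular sheaths
appear as bright parallel stripes. `estimateOrientationHough()` finds
their axial direction by thresholding (Otsu — parameter-free; the source
only says the grayscale was thresholded) and Hough-style voting:
foreground pixels are projected onto candidate normals and the angle
whose 1-px-bin vote histogram is most sharply banded wins, refined to
0.1°. Two details matter numerically: votes are splatted linearly over
the two adjacent bins (integer rounding produces resonance spikes at
rational slopes that can out-score the true angle), and the histogram is
averaged over 3 bins before scoring (aliasing combs live at the 1–2 bin
scale; true stripe bands span ≈ period·cos θ ≈ 11–14 bins). At most
20 000 foreground pixels vote, evenly subsampled — orientation estimates
on 512-px fields change by < 0.2° while the pipeline stays fast.
`peritubuleWidth()` then samples 10 intensity profiles along the normal
(bilinear interpolation, 1-px steps), median-filters them over 3 px,
detects local minima with prominence ≥ 10% of the profile's dynamic
range, and reports the median consecutive-valley spacing in µm. Valley
positions are refined to sub-pixel accuracy by a parabolic fit on the
*unfiltered* profile — the running median flattens smooth valley bottoms
and would otherwise quantize spacings to whole pixels, biasing the
age-slope. "Size" here is the stripe *period* (valley-to-valley), exactly
as the cross-section procedure defines it; this conflates ridge width and
gap, a known ambiguity of the method. The number of sections and the
valley detector are package decisions; the source names tops and valleys
but no detector.

**Structural dispersion (SD).** `structureTensorSD()` smooths the image
(σ = 0.5 µm), forms the gradient outer-product tensor, smooths it again
(σ = 2 µm — below and above the stripe-period scale respectively), and
takes the per-pixel orientation φ = ½·atan2(2J_xy, J_yy − J_xx). SD is
the coherence-weighted circular standard deviation of the doubled angles,
halved — `sqrt(-2 log R̄)/2` — capped at the 90° axial bound. The
alternative bounded "angular deviation" formula tops out at 40.5° and
could never express the disorganized class, so the unbounded-but-capped
form is used. Classification: SD ≤ 20° organized, SD > 40° disorganized,
partial in between; the boundaries are asserted exactly in the tests.
A border margin of three tensor sigmas is excluded (the FFT convolution
wraps), and angles are axial (180°-periodic) throughout, measured
counter-clockwise from the image row axis with the origin at top-left.

**Hyperpolarizability ratio ρ.** Under the standard cylindrical-symmetry
model of collagen SHG, the intensity at incident linear polarization α
with fibers at θ is

$$I(\alpha) = K\,p\,\{\sin^2[2(\alpha-\theta)] +
  [\sin^2(\alpha-\theta) + \rho\cos^2(\alpha-\theta)]^2\},$$

so parallel excitation gives $Kp\rho^2$ and perpendicular gives $Kp$.
The source cites but does not print this model; it is the standard one
behind the "two states for the magnitude, the third for the sign"
acquisition at 0°/90°/60°. `rhoMap()` inverts it exactly: the ratio of
the orthogonal pair yields a quadratic in ρ whose two roots are the
candidates (the unknown $Kp$ cancels, as does the shared
$\sin^2 2\Delta$ term), and the oblique state votes for the root whose
predicted intensity ratio matches. In the fiber-aligned frame this
reduces to $|\rho| = \sqrt{I_\parallel/I_\perp}$ plus a sign vote, which
`rhoMagnitude()` and `rhoSign()` expose directly. All ratios are taken
against the perpendicular state, so no inter-image calibration is
assumed beyond co-registration, and the sign is invariant to global
intensity rescaling (the default noise floor is relative, 1% of the
reference state's maximum; raising the floor only ever masks more
pixels).

*Identifiability caveat.* The response is even in (α − θ). With states
at 0°/90°/60°, fiber orientations θ ∈ {30°, 75°, 120°, 165°} make the
oblique state an exact mirror of one orthogonal state: both quadratic
roots then reproduce all three intensities to machine precision and ρ is
genuinely unidentifiable — no estimator can do better. `rhoMap()` raises
a diagnostic error within 1° of these geometries rather than returning a
silently arbitrary root. In practice the acquisition aligns the
polarization basis with the quasi-parallel tubules (θ ≈ 0), far from the
degenerate set. Per-pixel inversion followed by spatial averaging is the
default summary; inverting the image-averaged intensities is available
via `rhoMap(summary = "image_mean")` since the source's wording admits
both readings.

## The synthetic generator

`generateTubuleField()` renders the peritubular stripes as a
raised-cosine profile raised to the power that sets the ridge full width
at half maximum to `duty` periods (default 0.5). This keeps a unique
smooth minimum per period — exactly one valley every `periodUm` — which
is what the width procedure assumes; flat-bottomed profiles would make
"the" valley position ill-defined. Orientation jitter is applied by
warping the stripe phase with a smooth Gaussian random field (correlation
length 10 µm) whose along-stripe slope has standard deviation
tan(jitter), so the local stripe orientation deviates from the nominal
axis with sd ≈ the requested degrees; the tests confirm the
structure-tensor SD reads back 10° ± 2° at 10° of jitter.
`generatePatchworkField()` tiles 8 × 8 independently oriented patches to
emulate a non-organized arrangement.

`renderChannelPair()` builds TPEF as `tpefMean · (bg + (1-bg) · pattern)`
and SHG as `shgTpefRatio` times that, so the ratio of spatial means
equals the target *by construction*; noise is Poisson (photon) plus
Gaussian (read), quantized to the 16-bit detector range. Noiseless
renders skip quantization and stay continuous — the ratio-conservation
and 10⁻⁶ ρ-round-trip guarantees are incompatible with integer
quantization, and the noiseless path exists precisely to give exact
ground truth. `renderPolarimetricStack()` applies the polarization
response above at the three configured angles.

`generateCohort()` draws per-specimen ground truths as
`line(age) + N(0, residualSd)` for width, INAG and ρ, back-solves the
per-region rendering ratio from the target INAG via
`r = (1 + INAG)/(1 − INAG)`, and renders 5 regions per specimen
(matching the acquisition protocol). Defaults: 9 specimens at ages
evenly spanning 19–82 (the study's age range), the three printed aging
lines (width 0.03·age + 3.47 µm; INAG −0.003·age − 0.25;
ρ −0.02·age − 1.03), zero residuals, 512 px over 180 µm
(0.3516 µm/px — the source does not state the pixel count; this resolves
the smallest ≈ 4 µm period with > 11 px), noiseless rendering. Residuals
default to zero because the recovery experiments are defined on the
lines themselves and the real specimens' scatter is not tabulated
anywhere to calibrate against; realistic scatter is opt-in. The sex
split defaults to 4 M / 5 F: the source's counts are internally
inconsistent (N = 9 but "4 men and 9 women"), so the generator exposes
both the cohort size and the split as configuration and takes no side.

What the generator does *not* emulate: optical point-spread blur and
3-D sectioning, enamel and the dentine–enamel junction, tubule curvature
and branching, depth-dependent signal loss, and pathology. Passing
recovery tests therefore demonstrates that the estimators are unbiased
and stable on geometry that satisfies their assumptions — not that those
assumptions hold on any particular real specimen.

## Statistics

Specimens, not regions, are the regression units (each specimen enters
as the unweighted mean of its regions, matching how the per-specimen
symbols are defined in the study's figures); region-level regression is
available by calling `fitAgeRegression()` on the region table.
`fitAgeRegression()` is ordinary least squares with the Pearson
correlation and its two-sided t-test p-value; no multiple-testing
correction is applied (none is applied in the source). n ≥ 3,
non-constant ages and non-constant values are required, otherwise the
fit is refused with a message. `relativeChange()` evaluates the fitted
line at two ages and reports the percent change *in magnitude* — for a
negative index like INAG, "58% larger" can only mean |line(80)| vs
|line(20)| (0.49 vs 0.31), and only this reading reproduces the printed
figure; the signed change is reported alongside and zero crossings are
flagged. `sexComparison()` is a two-sided Mann–Whitney U, exact for
small tie-free samples, mid-rank normal approximation (no continuity
correction, so identical groups give p = 1) otherwise.

## Numerical choices and degenerate inputs

- Stripe periods at or below 2 px are rejected at construction with a
  message naming the Nyquist limit.
- Uniform or isotropic images raise "no dominant orientation" from the
  Hough estimator (mean structure-tensor coherence below 0.3; aligned
  synthetic fields measure ≥ 0.7, white noise ≈ 0.16).
- Constant images are rejected by the structure tensor; all-zero channel
  pairs are rejected by the INAG summary.
- INAG values outside (−1, 1) cannot be encoded as a ratio and are
  rejected when drawing cohorts.
- ρ: pixels below the noise floor, quadratic roots with negative
  discriminant (possible under noise), near-zero |ρ| and tied sign votes
  are masked, never guessed; summaries are over unmasked pixels.
- All random draws go through an internal seed guard that restores the
  caller's RNG state, so identical configurations and seeds give
  bit-identical images, tables and CSV outputs (asserted by checksum in
  the tests).

## Problem sizes used in the test-suite

Unit tests run on 32–256 px fields at the standard 0.3516 µm pixel; the
end-to-end recovery experiments use the full study geometry — 9
specimens × 5 regions at 512 px — once for the TPEF/SHG pairs and once
for the polarimetric stacks, and the organization checks use 10 aligned
plus 10 patchwork fields at 512 px. These sizes were chosen as the
smallest at which each property is cleanly measurable.

## Worked example

```{r example}
library(dentineMP)

# one synthetic field and its measurements
f <- generateTubuleField(tubuleFieldParams(periodUm = 5), seed = 1)
pair <- renderChannelPair(f, channelRenderParams(shgTpefRatio = 0.57))
inagSummary(pair$shg, pair$tpef)            # (0.57-1)/(0.57+1) = -0.2739
theta <- estimateOrientationHough(pair$shg) # 0
peritubuleWidth(pair$shg, theta)$widthUm    # 5.00
structureTensorSD(pair$shg)$orgClass        # "organized"

# a small cohort end to end
cfg <- runConfig(cohortConfig(agesYears = c(20, 40, 60, 80),
                              regionsPerSpecimen = 2, nPx = 256,
                              fieldUm = 90),
                 orientation = "known")
res <- runPipeline(cfg)
res$regressions$width_um   # slope 0.030, intercept 3.47, R = 1
```

## Known limitations

- The width metric is a stripe period, not the electron-microscopy
  tubule-lumen diameter; comparisons across modalities are interpretive.
- ρ is unidentifiable at the four mirror orientations of the 0/90/60
  angle set (diagnosed, not resolved); acquisitions should keep the
  polarization basis roughly aligned with the tubules.
- The pipeline assumes co-registered, equally sized channels and makes
  no attempt at registration or flat-field correction.
- Real printed correlation strengths (R ≈ 0.83–0.95) depend on the real
  specimens' scatter, which is not tabulated; the package recovers the
  *lines*, and treats the correlation values as context.
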