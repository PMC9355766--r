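# dentineMP

Quantitative analysis of human dentine aging from multiphoton microscopy,
for forensic age estimation research. Dentine emits both two-photon
excited fluorescence (TPEF) and, from its collagen, second harmonic
generation (SHG); with age the peritubular sheaths thicken, the SHG/TPEF
balance shifts, and the collagen's internal order changes. dentineMP
measures all three from co-registered image pairs and
polarization-resolved SHG stacks, and regresses them on age.

The four estimators:

- **INAG** (index of aging), the normalized channel contrast
  `(Ĩ_SHG − Ĩ_TPEF) / (Ĩ_SHG + Ĩ_TPEF)` with Ĩ the spatial mean
  intensity, as a per-image scalar (`inagSummary`) and a spatially
  resolved map (`inagMap`); related to the SHG/TPEF mean ratio r by
  `INAG = (r − 1)/(r + 1)`.
- **Peritubule size**: dominant tubule orientation by thresholding +
  Hough voting (`estimateOrientationHough`), then intensity profiles
  perpendicular to the tubules whose consecutive intensity valleys are
  the stripe boundaries; the median valley spacing in µm is the size
  (`peritubuleWidth`).
- **Structural dispersion (SD)**: the coherence-weighted axial circular
  standard deviation of structure-tensor orientations, in degrees
  (`structureTensorSD`); SD ≤ 20° organized, SD > 40° disorganized.
- **ρ (hyperpolarizability ratio)**: signed, inverted pixelwise from
  three linear-polarization SHG images (0°/90°/60°) under the
  cylindrical-symmetry response
  `I(α) = K p {sin²[2(α−θ)] + [sin²(α−θ) + ρ cos²(α−θ)]²}` — the
  orthogonal pair gives the candidate values, the oblique state the sign
  (`rhoMap`, `rhoMagnitude`, `rhoSign`).

`fitAgeRegression` fits each per-specimen metric on age (OLS + Pearson),
`relativeChange` turns a fitted line into "X% larger at age 80 than at
20" statements, and `sexComparison` is the Mann–Whitney U test. Because
no real tooth images are publicly deposited, the package ships a
synthetic generator (`generateTubuleField`, `renderChannelPair`,
`renderPolarimetricStack`, `generateCohort`) that produces whole cohorts
with known ground truth on configurable aging lines, so the entire
pipeline is validated by parameter recovery. `runPipeline` orchestrates
simulate → per-region analysis → per-specimen aggregation → regressions
with fully reproducible, seed-deterministic outputs; images travel as
single-channel TIFFs with JSON metadata sidecars
(`writeCohort`/`readMPImage`/`validateInputs`).

## Worked example

```r
library(dentineMP)

# one 180 x 180 um synthetic dentine field, stripes 5 um apart
f <- generateTubuleField(tubuleFieldParams(periodUm = 5), seed = 1)
pair <- renderChannelPair(f, channelRenderParams(shgTpefRatio = 0.57))

shgTpefRatio(pair$shg, pair$tpef)            # 0.57
inagSummary(pair$shg, pair$tpef)             # -0.2738854
theta <- estimateOrientationHough(pair$shg)  # 0
peritubuleWidth(pair$shg, theta)$widthUm     # 4.999535
structureTensorSD(pair$shg)$orgClass         # "organized"

st <- renderPolarimetricStack(f, polarimetricRenderParams(rho = -1.25))
rhoMap(st, thetaDeg = theta)
#> RhoMap 512 x 512 px: mean -1.2500, sd 0.0000, theta 0.0 deg (0.0% masked)

# a 4-specimen cohort end to end
cfg <- runConfig(cohortConfig(agesYears = c(20, 40, 60, 80),
                              regionsPerSpecimen = 2, nPx = 256,
                              fieldUm = 90),
                 orientation = "known")
res <- runPipeline(cfg)
res$regressions$width_um
#> AgeRegression [width_um]: width_um = 0.03001 * age + 3.47  (R = 1.000, p = 3.3e-10, n = 4)
res$regressions$inag
#> AgeRegression [inag]: inag = -0.003 * age + -0.25  (R = -1.000, p = 0, n = 4)
res$regressions$rho_mean
#> AgeRegression [rho_mean]: rho_mean = -0.02 * age + -1.03  (R = -1.000, p = 0, n = 4)
relativeChange(res$regressions$inag, 20, 80)$percentMagnitude
#> 58.1
```

The ratio 0.57 reproduces itself because noiseless renders conserve the
configured SHG/TPEF mean ratio exactly; the width estimator reads the
5 µm stripe period back to a hundredth of a micron; and the regressions
recover the configured aging lines (slope 0.03 µm/yr for width,
−0.003/yr for INAG, −0.02/yr for ρ) because the cohort ground truths are
generated on those lines with zero residual — the point of the recovery
design is that any pipeline bias would show up as a slope or intercept
deviation.

A thin command-line front end over the same functions lives at
`inst/scripts/dentinemp.R` (subcommands `simulate`, `analyze`,
`validate`).

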