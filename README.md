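# seagrassRS

Semi-automated monitoring of subtidal seagrass from multispectral
satellite-like imagery, for coastal remote-sensing and blue-carbon
researchers. The package covers the full analysis chain — and ships a
synthetic scene generator built on the same optical model, so every
stage runs and is tested without downloading any satellite data:

* **simulate** — bathymetry, five-class truth maps (land, optically-deep
  water, seagrass, submerged sand, intertidal), a smooth seagrass LAI
  field, training regions of interest and climate covariates;
* **preprocess** — dark-object-subtraction atmospheric correction using
  the darkest NIR water pixel, plus scanline-gap in-painting;
* **classify** — a small per-pixel neural classifier (balanced training,
  90/10 stratified split), a 2.5 m optically-deep mask, areal extent at
  900 m² per 30 m pixel, and exact Shapley band importance;
* **optics / carbon** — water-column inversion of the green band to
  bottom reflectance and leaf area index, cross-sensor brightness
  calibration, and conversion to biomass and belowground organic carbon;
* **trends** — seasonal Mann–Kendall, Theil–Sen slopes, trend
  detectability (γ), per-pixel seagrass frequency maps and
  climate-driver regression;
* **agreement** — precision/recall/F, overall accuracy, Cohen's κ and
  the McNemar test between presence/absence maps.

## The model at the core

Over a submerged bottom, green-band (560 nm) remote-sensing reflectance
follows the two-path attenuation law

$$R_{rs} = \frac{R_b}{\pi}\,e^{-(K_d+K_{Lu})H},\qquad K_{Lu}=\frac{K_d}{2\pi},$$

with water column height `H` (tide-adjusted depth) and bottom
reflectance `R_b`. Retrieval inverts it and applies the log-linear LAI
model `LAI = max(a + b·ln R_b + c, 0)` (b < 0: denser canopies are
darker). Carbon follows the fixed transfer chain

```
fresh biomass = 500 g m⁻² × LAI        dry = 0.2 × fresh
AG carbon     = 0.34 × dry             BG carbon = 3 × AG carbon
```

so one unit of LAI stores 102 g C m⁻² belowground. Trend testing uses
the seasonal Mann–Kendall statistic with tie-corrected variance,
Theil–Sen slopes, and the detectability form
`n* = [3.3·σ_N/|ω| · √((1+φ)/(1−φ))]^(2/3)`.

## Worked example

Simulate a lagoon scene, correct it, train the classifier, and push one
scene through extent, LAI and carbon:

```r
library(seagrassRS)
cfg   <- sceneConfig(seed = 7L)            # 96 x 96, 30 m pixels
dem   <- generateDem(cfg)
truth <- generateTruth(cfg, dem)
scene <- renderScene(truth, cfg)
corr  <- dosCorrect(scene, findDarkOffset(scene, !is.na(dem)))

rois  <- makeRois(truth, cfg)
ts    <- balanceClasses(extractTraining(corr, rois), nPerClass = 4000, seed = 1)
sp    <- splitTrainTest(ts, 0.9, seed = 2)
model <- trainClassifier(sp$train, config = list(size = 16, maxit = 150, seed = 3),
                         test = sp$test)
model
#> ClassifierModel: 5 classes, 6 bands, hidden size 16
#>   training accuracy: 1 | held-out accuracy: 1

cmap <- applyDepthMask(predictMap(model, corr), dem, cfg@tideHeight)
ext  <- computeExtent(cmap)
ext
#> Seagrass extent: 2293 pixels = 2.0637 km^2 ( 900 m^2/pixel )

lai <- retrieveLai(corr, cmap, dem)
carbonSummary(lai, ext)
#> CarbonSummary over 2.0637 km^2, mean LAI 1.614
#>   fresh 1.666 Gg | dry 0.333 Gg | AG C 0.1133 Gg | BG C 0.3398 Gg | total C 0.4531 Gg
#>   BGC density: 164.67 g C m-2
```

The classifier recovers the truth map essentially perfectly at the
default class contrast and sensor noise; the retrieved mean LAI (1.614)
matches the simulated field's mean, and at that density the meadow
stores ~165 g C m⁻² belowground. Scaled to a 23 km² bay at mean LAI
1.6, the same chain gives 18.4 Gg fresh biomass, 3.7 Gg dry, 5.0 Gg
total carbon and 3.8 Gg belowground carbon:

```r
carbonSummary(1.6, 23)
```

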