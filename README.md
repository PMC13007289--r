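# apaSim

Annihilation-photon acollinearity (APA) in PET is commonly summarized as
"Gaussian with a FWHM of ≈0.5°". That sentence has two readings, and they
are not equivalent:

* **GaussMag** — the *magnitude* θ of the acollinearity angle is drawn
  from a Gaussian. Then θ is half-normal and the 2D angular deviation
  (φ, ψ) has density g ∝ N(θ; 0, σ)/θ — a cusp, singular at zero.
* **GaussDev** — the 2D *deviation* (φ, ψ) is an isotropic Gaussian with
  per-axis σ = FWHM/2.35482. Then θ = √(φ²+ψ²) is Rayleigh(σ). This is
  the reading consistent with angular-correlation measurements.

The two densities are linked by f(θ) = 2πθ·g(φ, ψ). Several PET Monte
Carlo packages implement the first reading. Because the image-space point
response induced by APA is g scaled by R/2 (R the scanner radius), the
misreading matters: under GaussDev the blur is a Gaussian of FWHM
radians(0.58°)/2 · R ≈ 0.0051·R — 2.05 mm at an 81 cm ring — while under
GaussMag it is a cusp whose half-max width is ~0.4–0.5 mm, a five-fold
underestimate of the apparent resolution loss.

`apaSim` is a self-contained 2D PET simulation laboratory for comparing
the two readings end to end, aimed at people who build or validate PET
Monte Carlo codes and reconstruction pipelines:

* samplers and analytic densities for both interpretations, plus the
  rotation construction of the deviated photon (`sampleDeviation`,
  `magnitudePdf`, `deviationPdf`, `deviationToDirection`, `makePair`);
* a polygonal 2D ring scanner (default: 40 sides × 128 crystals of
  0.5 mm, ≈81 cm face-to-face) with idealized front-face detection
  (`ringScanner`, `detect`, `enumerateLors`);
* phantoms — point source over a uniform background disk, sectored
  hot-spot phantom with 0.5–2.5 mm spots at 4:1 — with exact emission
  sampling and ground-truth rasters (`pointPhantom`, `hotSpotPhantom`,
  `sampleEmission`, `groundTruth`);
* a seeded true-coincidence simulator (`simulateCoincidences`,
  `thetaHistogram`);
* Siddon ray-traced system matrices and ML-EM reconstruction with
  MSE-optimal iteration selection (`buildSystemMatrix`, `mlem`,
  `mseOptimalIteration`);
* resolution metrics: analytic APA blur (`theoreticalFwhm`), Monte Carlo
  displacement metrics (`fwhmEquivalent` — the 29.2%-mass width for
  cusped responses — and `stddevBlur`), blur-vs-diameter tables
  (`blurCurve`), quadrature combination (`quadratureResolution`),
  profile FWHM and histogram fits, and Rayleigh-criterion hot-spot
  resolvability (`resolvability`);
* end-to-end experiments (`pointSourceExperiment`, `hotSpotExperiment`)
  and a thin CLI (`inst/scripts/apasim.R`) with simulate / reconstruct /
  blur-curve / t19-check subcommands.

## Worked example

Classify an unknown simulator stream from its θ-histogram, and tabulate
the predicted blur at the whole-body scale:

```r
library(apaSim)

set.seed(1)
dev <- sampleDeviation(apaModel("GaussMag", acoFwhmDeg = 0.58), 1e6)
chk <- t19Check(dev$theta)
chk$verdict
#> [1] "GaussMag"
chk$gaussian@fwhm       # fitted magnitude FWHM, degrees
#> [1] 0.5804812

blurCurve(c(200, 810, 1000), n = 1e6, seed = 1)
#>   diameter_mm gaussdev_fwhm_mm gaussmag_fwhm_equiv_mm gaussmag_std235_mm
#> 1         200        0.5061455              0.1609705          0.3579925
#> 2         810        2.0498892              0.6519304          1.4498697
#> 3        1000        2.5307274              0.8048524          1.7899626
```

Reading the 810 mm row: if the deviation is the Gaussian (GaussDev), APA
alone blurs a whole-body image by 2.05 mm FWHM. If a simulator instead
draws the magnitude from that Gaussian (GaussMag), the same nominal 0.58°
produces a cusp whose 29.2%-mass width is only 0.65 mm — the
misinterpretation hides about three quarters of the blur — while
pretending the cusp were Gaussian (std × 2.355) would claim 1.45 mm.

The imaging counterpart (several minutes each):

```r
psf <- pointSourceExperiment(apaModel("GaussDev"), seed = 1)
psf$fwhmGaussFit   # ~2.0-2.1 mm across seeds, vs 2.05 mm theoretical
cusp <- pointSourceExperiment(apaModel("GaussMag"), seed = 2)
cusp$fwhmHalfMax   # ~0.45-0.50 mm cusp width
```

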