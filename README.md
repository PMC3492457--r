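# rtcakinetics

Model-based analysis of real-time cell analysis (RTCA) impedance monitoring
for photodynamic therapy (PDT) screens.

Impedance biosensor plates report a dimensionless cell index,
CI = (Z_i − Z_0)/15, every few minutes for days, producing hundreds of
kinetic profiles per experiment. For screens that cross a photosensitizer
concentration *C* (µM) with a light fluence *F* (J/cm²), the question is not
only *whether* cells die but *how fast* and *whether they regrow* — which
single end-point viability assays cannot resolve. `rtcakinetics` implements
a two-part statistical workflow for such plates:

1. **Where to look.** Normalized CI profiles (NCI, fixed to 1 at a reference
   time t₀) over a study window are submitted to a MANOVA with canonical
   analysis: the eigenstructure of W⁻¹B (between- over within-group scatter)
   projects every measurement instant into a canonical map, and the instants
   farthest from t₀ on the first two axes become the regions of interest
   T1 and T2, each then tested with a classical one-way ANOVA.
2. **What the kinetics say.** Post-irradiation CI is log-transformed to the
   transformed cell index x(t) = ln(y(t)/y(t_irr)) and fitted per well with
   the exponential-linear model

   x(t) = x₀ − k·(1 − e^(−t/T)) + r·t + e(t),   e(t) ~ N(0, σ²)

   where **T** (h) is the time constant of the transient decrease, **k** its
   magnitude, and **r** (h⁻¹) the steady-state growth rate. Estimation is
   bounded nonlinear least squares (Levenberg–Marquardt) with deterministic
   multi-starts, a nested F-test guard for the unidentifiable flat-profile
   regime, and a two-stage method-of-moments mixed-effects summary across
   replicate wells. Treatments are finally classified in the (log₁₀T, r)
   plane — log₁₀(T) < 0 and r < 0 marks an efficient photodynamic response —
   and cross-tabulated against the interaction rule C·F ≥ 2.5 µM·J/cm².

A seeded plate simulator (`simulatePlate()`) generates full factorial
experiments — 6 concentrations × 4 fluences × 6 replicates by default — with
recorded ground truth, supporting parameter-recovery and end-to-end
validation without access to instrument data.

## Worked example

```r
library(rtcakinetics)

pm   <- factorialPlateMap()                         # 24 treatments, 144 wells
sim  <- simulatePlate(generatorConfig(seed = 42))   # seeded synthetic plate
fits <- fitPlate(sim$traces, pm)                    # per-well kinetic fits
#> fitPlate: 142/144 wells converged
rep  <- synergyReport(fits)
rep
#> SynergyReport: 24 treatments, 7 called efficient
#>          cfAboveCut
#> efficient FALSE TRUE
#>     FALSE    17    0
#>     TRUE      0    7
subset(rep@treatmentCalls, efficient, select = c(label, cf, logT, r_per_h))
#>       label    cf    logT  r_per_h
#> 12   C10_F1  10.0 -0.2357 -0.02339
#> 16  C0.5_F5   2.5 -0.0848 -0.00768
#> 17    C1_F5   5.0 -0.1882 -0.01714
#> 18   C10_F5  50.0 -0.2801 -0.02850
#> 22 C0.5_F10   5.0 -0.1837 -0.01779
#> 23   C1_F10  10.0 -0.2324 -0.02338
#> 24  C10_F10 100.0 -0.2963 -0.02950
```

The agreement table is diagonal: the seven treatments called efficient from
their fitted kinetics (log₁₀T < 0 *and* r < 0) are exactly the seven with
C·F ≥ 2.5 µM·J/cm². Region selection on a six-concentration series:

```r
demo <- generatorConfig(design = factorialPlateMap(fluences = 10),
                        seed = 42, sigma = 0.05, postH = 96)
nci  <- TraceSet(lapply(as.list(simulatePlate(demo)$traces),
                        normalizeCI, t0 = 25))
pmx  <- buildProfileMatrix(nci, demo@design, window = c(25, 120))
cr   <- manovaCanonical(pmx)
cr
#> CanonicalResult: 30 axes (5 meaningful), first two capture 100.0% of variance
selectRegions(cr, t0 = 25)
#> RegionsOfInterest: T1 = 28.5 h (axis 2), T2 = 87.25 h (axis 1)
```

The first two canonical axes carry essentially all of the between-group
discriminant variance; the axis-1 pick (T2) lands late in the window, where
concentration groups have diverged most, and `anovaAtTime(pmx, 87.25)`
confirms a strong concentration effect there (F(5, 30) ≈ 1e4).

A pipeline wrapper `runPipeline()` (and the thin CLI in
`inst/scripts/rtca-kinetics.R`) chains
simulate → preprocess → select-regions → fit → classify with seeded,
byte-reproducible artifacts. See `vignettes/rtca-kinetics-methods.Rmd` for
the modelling details and design choices.

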