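---
title: "Model-based analysis of impedance cytotoxicity kinetics: methods and design choices"
author: "rtcakinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of impedance cytotoxicity kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcakinetics)
```

## The measurement and its scales

Impedance-based real-time cell analyzers report a dimensionless cell index

$$\mathrm{CI}(t) = \frac{Z_t - Z_0}{15},$$

where $Z_t$ is the well impedance and $Z_0$ its background before seeding.
CI is proportional to the electrode area covered by attached cells, so it
tracks adhesion, proliferation and death continuously — typically every
15 min (0.25 h) for several days. `impedanceToCI()` implements the
conversion; negative CI (impedance below background) is passed through but
flagged, since it carries information about detached, dead wells.

Three derived scales are used downstream, each an explicit, invertible
operation:

* **NCI** — `normalizeCI(trace, t0)` divides a trace by its value at a
  reference instant $t_0$, so every well starts the study window at exactly
  1 and wells with different seeding densities become comparable.
* **TCI** — `transformCI(trace, originT)` applies
  $x(t) = \ln\!\big(y(t)/y(t_{\mathrm{origin}})\big)$ with the origin at
  irradiation time. The log-ratio is chosen because undisturbed,
  post-transient CI growth is close to exponential, so the steady state
  becomes a straight line on the transformed scale — the property the
  kinetic model below exploits. The transform is a pluggable strategy: any
  monotone variance-stabilizing alternative (e.g. a power transform) can be
  substituted without touching the fitter, which only sees a `TCITrace`.
* `inverseTransform()` maps TCI back to CI exactly (round-trip error below
  $10^{-12}$, enforced by tests on 1,000 random traces).

Times are hours everywhere, stored as decimals (15 min = 0.25 h). Three
clock origins — seeding, exposure, irradiation — are supported, and
conversions between them are explicit (`convertClock()`), never implicit,
because analyses switch between time-since-exposure windows (region
selection) and time-post-irradiation windows (kinetic fitting).

## Selecting informative time regions

With hundreds of correlated time points per well, testing every instant is
hopeless; the package instead asks *which instants separate the treatment
groups best*. `buildProfileMatrix()` assembles an $n \times p$ matrix of
NCI values (wells × instants) over a study window (default [25, 120] h),
and `manovaCanonical()` solves the generalized eigenproblem of the
between-group over within-group scatter, $W^{-1}B$, via a Cholesky
whitening of $W$ (numerically, a symmetric eigenproblem — tests verify the
eigenvalues against a brute-force `solve(W) %*% B` eigensolve to
$10^{-10}$). Because group mean profiles are generated by a three-parameter
kinetic model, the between-group structure is low-rank and the first two
canonical axes typically capture essentially all discriminant variance.

Numerical choices:

* **Rank handling.** With $p \gg n$ the within scatter is singular. The
  default is uniform thinning of the time grid to at most $n - g$ columns
  ($g$ groups); ridge shrinkage $W + \lambda I$ with
  $\lambda = \mathrm{shrinkage}\cdot\mathrm{tr}(W)/p$ is exposed as an
  alternative for users who prefer to keep the full grid. Neither is
  claimed to be canonical — the choice is documented, not hidden.
  Note that with $p$ close to $n-g$ the within scatter is estimated on few
  degrees of freedom and even null data can show large leading eigenvalues;
  thinning well below the bound is advisable when group separation is weak.
* **Degenerate columns.** The normalization instant has *exactly* zero
  variance (every NCI value is 1), which alone makes $W$ singular;
  `buildProfileMatrix()` drops constant columns with a message, and the
  canonical map treats $t_0$ as the origin (coordinate 0) when its column
  is absent.
* **Map coordinates.** The per-instant coordinates are structure
  coefficients — the correlation of each time variable with each canonical
  score — which makes "projecting the instants into the map"
  scale-invariant and interpretable. Raw loadings are available from the
  `axes` slot.
* **Orientation.** Each axis is flipped so the earliest analyzed instant
  has a non-positive coordinate, making plots and picks deterministic.

`selectRegions()` picks, per axis, the instant farthest from $t_0$'s
coordinate: the axis-1 pick is the late region T2, the axis-2 pick the
earlier region T1. Ties go to the earlier instant; if both axes agree, the
axis-2 pick moves to its next-farthest instant so T1 ≠ T2. Distance is
per-axis rather than Euclidean in the plane, because each axis is read as
its own region; this is a genuine design choice and the per-axis reading is
the package's default. `anovaAtTime()` then runs a classical fixed-effects
one-way ANOVA at each pick. No multiple-testing correction is applied
across the two instants — raw p-values are reported, and tests verify the
nominal 5% type-I error over 2,000 null simulations (6 groups × 6
replicates).

## The exponential-linear kinetic model

Post-irradiation TCI profiles decompose into a transient disturbance and a
steady-state trend:

$$x(t) = x_0 - k\,(1 - e^{-t/T}) + r\,t + e(t), \qquad e(t) \sim
\mathcal N(0, \sigma^2),$$

with $t$ measured from irradiation. $T$ (h) is the time constant of the
transient decrease — small $T$ means rapid photodynamic killing; $k$
(dimensionless, $\ge 0$) its magnitude, entering with a negative sign so
larger $k$ means a deeper CI drop; $r$ (h⁻¹) the steady-state growth rate —
negative $r$ means the culture keeps declining instead of regrowing. $x_0$
is estimated rather than pinned to its theoretical value 0 so that noise at
the transform origin and origin-snapping error are absorbed by the
intercept instead of biasing $k$.

`fitWell()` estimates $(x_0, k, T, r)$ by bounded Levenberg–Marquardt least
squares (`minpack.lm::nlsLM`), with:

* **Data-driven starts** — $r$ from a straight line through the last third
  of the profile; $k$ from the gap between the first sample and that line's
  intercept (the algebraic estimate of $x_0 - (x_0 - k)$); $T$ from the
  first crossing of the $1 - e^{-1}$ transient level; $x_0$ from the first
  sample.
* **A deterministic multi-start schedule** — up to 10 multiplicative
  perturbations of the $(T, k)$ starts covering fast/slow and shallow/deep
  regimes. A fixed schedule rather than random jitter keeps fits
  bit-reproducible regardless of the caller's RNG state.
* **Bounds** — $T \in [\text{sampling step}, 10\times\text{span}]$,
  $k \in [0, 10\times\mathrm{range}(x)]$, $r$ and $x_0$ free.
* **A flat-profile guard** — when the transient magnitude is small the
  $(k, T)$ pair degenerates into a ridge ($k(1-e^{-t/T}) \approx kt/T$
  trades off against $r$). The fitter therefore always tests the full model
  against the nested line $x = x_0 + r t$ (F-test at the 5% level) and,
  when the transient is not supported, reports the parsimonious line with
  $k = 0$, flags `weakT`, and marks the fit converged. This is what makes
  control wells well-behaved instead of returning arbitrary ridge points.

$\sigma$ is estimated as $\sqrt{\mathrm{RSS}/(n-4)}$; the covariance,
Jacobian condition number and gradient norm are returned as diagnostics.
Validated accuracy under the default conditions (tests recompute these):
noiseless profiles are recovered to $10^{-6}$ relative error on all 144
wells; at $\sigma = 0.05$ with 120 points over 30 h, treatments with
$k \ge 0.5$ show median absolute relative errors below 10% per parameter
(200 Monte-Carlo replicates each); bias is below 2% at $\sigma = 0.01$.

`fitTreatmentMixed()` summarizes replicate wells with a two-stage
method-of-moments mixed model: fixed effects are the means of the per-well
estimates; random-effect variances are the between-well variance minus the
mean within-well sampling variance, floored at zero. A joint nonlinear
mixed-effects likelihood is a declared extension point, not the default —
with six replicates per treatment the two-stage estimator is transparent,
fast and adequate, and it never fails to converge. `fitPlate()` applies
the per-well fitter across a plate, isolating failures as flagged rows.

## Synergy read-out

`classifyFits()` and `synergyReport()` turn fitted parameters into
treatment calls. A *fast transient* is $\log_{10}(T\,[\mathrm h]) < 0$
(i.e. $T < 1$ h) and *suppressed growth* is $r < 0$; both comparisons are
strict, since the thresholds are read as "below the reference". A treatment
is *efficient* when both hold — the bottom-left corner of the
$(\log_{10} T,\ r)$ map. The interaction $C\!\cdot\!F$ (µM·J/cm²) uses
inclusive cuts ($\ge 2.5$, with a stricter $\ge 5$ also reported), and the
report cross-tabulates the efficient calls against the interaction rule.
Choices worth surfacing:

* The log base for $T$ is 10 (so the threshold 0 means $T = 1$ h); natural
  log is available via `synergyThresholds(logBase = exp(1))`, and the base
  is recorded in every report.
* $k$ has no natural threshold and is reported as a within-plate
  percentile, not a boolean.
* Treatment-level calls use the mean of converged replicate estimates;
  per-well calls are also returned. Non-converged fits yield an explicit
  `"undetermined"` status, never a silent exclusion.
* Both interaction cuts (2.5 and 5) are plain configuration; the package
  does not adjudicate between them.

## What the simulator emulates — and what it does not

`simulatePlate()` generates the full factorial screen: 6 photosensitizer
concentrations {0, 0.05, 0.1, 0.5, 1, 10} µM × 4 fluences {0, 1, 5, 10}
J/cm² × 6 replicates = 144 wells, sampled every 0.25 h. Each well has

1. a pre-irradiation growth phase: exponential CI growth from 0.2 over
   24 h (default rate $\ln(1.4/0.2)/24 \approx 0.081$ h⁻¹, ending near 1.4
   — a realistic sub-confluent cell-index level at irradiation);
2. post-irradiation kinetics following the exponential-linear model with
   treatment-specific ground truth;
3. optional artifacts: a washing dip at irradiation time
   (`injectWashingArtifact()`, off by default because it sits exactly at
   the fitting origin), and a linear late-decline term (off by default —
   the slow late toxicity of nanoparticles in darkness is real but its
   mechanism is not modeled here).

Noise is additive Gaussian on the TCI scale (default $\sigma = 0.05$),
i.e. multiplicative lognormal on CI, matching where the kinetic model
places its error term.

The ground-truth dose-response map ties the kinetic parameters to the
interaction $CF = C \cdot F$ through smooth saturating curves:

$$k = k_0 + k_{\max}\frac{CF^{h}}{EC_{50,k}^{h} + CF^{h}},\quad
T = T_{\min} + (T_{\max}-T_{\min})\frac{EC_{50,T}}{EC_{50,T}+CF},\quad
r = r_0 - r_{\mathrm{drop}}\frac{CF}{EC_{50,r}+CF}$$

with defaults $k_0 = 0.05$, $k_{\max} = 3$, $EC_{50,k} = 2.5$, $h = 2$,
$T \in [0.5, 10]$ h, $EC_{50,T} = 0.088$, $r_0 = 0.05$ h⁻¹,
$r_{\mathrm{drop}} = 0.08$ h⁻¹, $EC_{50,r} = 0.95$. The $T$ and $r$ scales
are deliberately calibrated so both threshold crossings ($T = 1$ h, $r = 0$)
occur at $CF \approx 1.58$ — the geometric midpoint between the design's
adjacent interaction levels 1 and 2.5. A single shared half-saturation
scale cannot place both crossings at the synergy boundary (it would leave
$T(2.5) \approx 5$ h, far above threshold), so each parameter gets its own
scale. Consequences, verified end-to-end by tests: treatments with
$CF \ge 2.5$ have ground-truth $\log_{10} T < 0$ and $r < 0$, those with
$CF \le 1$ do not, and the efficient-call set recovered from noisy fits
coincides exactly with the $CF \ge 2.5$ set.

Because the map depends on the interaction only (the invariants
$k(C, 0) = k(0, F) = k_0$ and monotonicity in $CF$ force this), treatments
sharing a $CF$ value share ground truth: the 24 treatments carry 11
distinct parameter triples. The simulator also deliberately omits: dark
cytotoxicity at $F = 0$ (concentration effects without light), mechanistic
photochemistry, electrode drift, edge effects, and well-to-well parameter
heterogeneity beyond the noise term (available only through the mixed-fit
recovery tests, which inject it explicitly). Passing tests therefore
demonstrate correctness of the estimators and of the decision rule under
the stated noise model — not robustness to every artifact of real
instrument data.

## Problem sizes and reproducibility

The test suite and the acceptance script run at the package's default study
sizes: 144-well plates (criteria on counting, noiseless recovery and
classification), a 36-well six-concentration series over [25, 120] h for
region selection, 200 Monte-Carlo replicates per treatment for noisy
recovery, and 2,000 simulations for the ANOVA null. All randomness flows
through explicit integer seeds; the simulator restores the caller's RNG
state, and the fitter uses no randomness at all. `runPipeline()` writes
every artifact with a stage/seed/config-hash provenance header and is
byte-reproducible for a fixed config and seed.

## Known limitations

* The log-ratio TCI transform assumes strictly positive CI; values at or
  below zero (dead wells) are floored at a configurable
  $\varepsilon = 10^{-3}$ with a per-well warning, which censors the depth
  of complete-kill profiles.
* The two-stage mixed model underestimates between-well variance when
  within-well sampling variance dominates (the floor at zero is then
  active); the factor-2 recovery guarantee in the tests reflects this.
* Canonical eigenvalues are overfit when the thinned grid size approaches
  $n - g$; treat the variance fractions as descriptive, not inferential.
* The synergy read-out is a threshold rule on fitted parameters, not a
  formal synergy model (no Bliss/Loewe surface fitting).
* Vendor binary exports of RTCA instruments are not parsed; input is
  plain delimited text.
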