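---
title: "Linking heat-stress climate indices to milk components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking heat-stress climate indices to milk components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmilk)
```

## The problem

Dairy cattle are sensitive to humid heat: above a thermal comfort zone, feed
intake drops, respiratory cooling increases, and milk yield and composition
respond. Field studies summarize the offending weather through bioclimatic
indices — combinations of air temperature, humidity, wind and solar radiation
calibrated against animal responses. Because every such index is a different
nonlinear lens on the same meteorology, they are strongly mutually
correlated, and the statistical question is which small subset of them best
explains monthly variation in milk yield, fat and protein.

`heatmilk` implements that inference chain end to end:

1. **Index engine** — six indices from daily meteorology:
   - THI (temperature-humidity index): `41.5 + T + 0.36 Td`;
   - ETI (equivalent temperature index): a full quadratic in `T`, `RH`, `V`
     with `T:RH` and `T:V` interactions;
   - ESI (environmental stress index):
     `0.63 T − 0.03 RH + 0.002 SR + 0.0054 T·RH − 0.073/(0.1+SR)`;
   - HLI and a modified HLI, built on the black-globe temperature
     `Tg = 1.33 T − 2.65 √T + 3.21 log10(SR+1) + 3.5`, the modified form
     switching regression planes at `Tg = 25 °C`;
   - RRP (respiratory rate predictor):
     `5.4 T + 0.58 RH − 0.63 V + 0.024 SR − 110.9`.
   A humidity chain supplies missing intermediates: saturation vapour
   pressure (Magnus form `6.1078 exp(17.1 T/(235+T))`), vapour pressure
   `1.6077 p q`, relative humidity `100·e/ew*`, and an eighth-root dew-point
   approximation `Td = (RH/100)^{1/8}(112+0.9T) + 0.1T − 112`.
2. **Preprocessing** — test-day milk record filters (days in milk 4–305,
   parity 3–6, no mastitis or dry-period records), monthly zone means,
   z-score normalization, and a stratified nonparametric bootstrap.
3. **Sparse model enumeration** — the LASSO objective
   `J(β) = (1/N) Σ (y − Xβ)² + λ Σ|β|` minimized by cyclic coordinate
   descent over a decreasing log-spaced λ grid; predictor subsets that
   persist over consecutive grid points become candidate models.
4. **Selection** — each candidate refit by OLS and scored with the Gaussian
   AIC `2k − 2 ln L`; near-ties within a ΔAIC window are co-selected and an
   Occam rule picks the fewest-predictor model among them.
5. **Validation** — leave-one-year-out cross-validation, Pearson r, the
   mean-squared-error skill score `MSES = 1 − MSE(Y′,Y)/MSE(Y,Ȳ)`, the
   root-mean-square prediction error `σest`, and normal Q-Q residual
   diagnostics.
6. **Synthetic study generator** — daily meteorology for three climate
   zones over 2002–2010 (April–September) and milk responses generated from
   known coefficients, so the whole chain is testable without external data.

## Conventions that matter

Several constants in the literature vary between sources; this package
implements one documented convention per choice.

- **RH scale.** All index formulas consume relative humidity in percent
  (0–100). The ratio `e/ew*` is therefore multiplied by 100.
- **Dew point.** The eighth-root approximation was chosen because it is the
  standard form that satisfies `Td = T` exactly at saturation and is monotone
  in RH; the package asserts both properties. It is an approximation to the
  Magnus inversion, adequate over the warm-season range.
- **Logarithms.** The heat-load indices use base-10 logarithms (their
  original definitions); a `log_base` argument allows natural-log
  sensitivity checks. The guard `+0.0001` inside the HLI log keeps calm-wind
  values finite, and `(0.82 V)^0.1` is defined as its limit 0 at `V = 0`.
- **Piecewise HLI.** The two branches of the modified HLI are defined by
  strict inequalities in the sources, leaving `Tg = 25` unassigned; the
  package assigns the boundary to the upper branch. The function is
  discontinuous there by construction.
- **Black-globe domain.** `√T` restricts `Tg` to `T ≥ 0 °C`; the package
  raises an error rather than extrapolate. The study window (April to
  September) keeps simulated temperatures well inside the domain.
- **THI constant.** The additive constant is implemented as 41.5 as printed
  in the index table this package follows; several THI variants in the
  literature use 41.2 instead. Comparisons across studies should check this
  constant.
- **Supersaturation.** Reanalysis-style inputs can be mutually inconsistent
  (`e > ew*`); RH is clipped to 100% with a warning rather than rejected.
- **Ta ≡ T.** Ambient temperature for ESI/RRP is the same 2 m temperature
  field as everywhere else.

## The LASSO stage

The objective uses a `1/N` scaling of the squared error (not `1/2N`), so the
coordinate-wise soft threshold sits at `λ/2` and the smallest all-zero
penalty is `λmax = 2·max_k |(1/N) Σ x_k y|`. These identities are asserted in
the tests against closed forms on orthonormal designs and against an
independent proximal-gradient (FISTA) minimizer on random correlated
instances (objective agreement 1e-8, coefficients 1e-5).

The solver is cyclic coordinate descent with covariance updates, implemented
in C++ for speed: each coordinate is set to its exact one-dimensional
minimizer, so the objective is non-increasing sweep by sweep (also asserted).
Convergence is declared when the largest coefficient change in a sweep drops
below `tol` (default 1e-7; default cap 1e5 sweeps, exceeded only for
pathological designs, in which case an error reports the stationarity gap).

The λ grid has 100 points, log-spaced down to `λmax·1e-4`, warm-started from
the previous solution. The grid density and floor are reporting choices, not
statistical ones: they control how finely support changes are resolved. A
support persisting for at least `persistence_m = 2` consecutive grid points
becomes a candidate; with ~100 grid points this keeps one-point transient
supports out while retaining every plateau a coarser reading would notice.
Both values are arguments.

No intercept is carried: predictors and predictand are z-scored first
(sample sd, N−1 denominator, per season with zones pooled), and the OLS
refit asserts its intercept is ~0. Normalization parameters are stored so
predictions can be mapped back to original units.

## AIC, the co-selection window and Occam

`AIC = 2k − 2 ln L` needs a likelihood convention; the package uses the
Gaussian maximized likelihood with `σ̂² = RSS/n`, giving
`AIC = 2k + n ln(2π RSS/n) + n` with `k = |support| + 2` (slopes, intercept,
variance). Absolute AIC values published under other conventions are not
comparable; ΔAIC values are, because any data-only additive term cancels —
the test suite verifies the package reproduces the published ΔAIC tables for
all six season × component comparisons from their printed AIC columns alone.

The co-selection window defaults to ΔAIC ≤ 1.0. Among co-selected models the
final pick is the one with fewest predictors (lower AIC breaks size ties).
This reproduces the published behaviour in both directions: near-ties at
ΔAIC 0.38 and 0.16 are co-selected, a model at ΔAIC 1.01 is not, and a
three-predictor model beats a four-predictor near-tie.

p-values of the overall F test are reported descriptively, uncorrected, as
in the tables this mirrors.

## Cross-validation

Folds are calendar years (nine folds for 2002–2010). Within each fold the
*training* rows alone define the normalization, the LASSO path, the
candidates and the AIC selection; held-out rows are transformed with the
training parameters, predicted, and mapped back to original units. Metrics
(r, MSES, σest, Q-Q) are pooled over all held-out pairs rather than averaged
per fold. A canary test asserts that corrupting a held-out row cannot change
that fold's fitted coefficients.

Re-running the full model search per fold is the default because it is the
leak-free reading of "select, then validate"; `fix_support` reproduces the
literal alternative (select once on all data, refit that support per fold),
which is cheaper and tighter but lets selection see the test years. The
residual sign convention is observed − predicted. The MSES reference mean is
the verification-sample mean.

In-sample, MSES on fitted values equals R² exactly for an OLS fit with
intercept (asserted to 1e-10); out-of-sample MSES is typically below R²,
which is the overfitting gap the score exists to expose.

## The synthetic study

The generator emulates the study conditions: 3 climate zones × 9 years
(2002–2010) × 6 months (April–September), daily, aggregated to 81 monthly
rows per season. Zones are a cool semi-arid highland (T 16 °C, RH 45%), a
mild humid coastal zone (21 °C, 75%) and a warm dry interior (26 °C, 30%) —
distinct climates of the kind the zoned design contrasts. Daily temperature
and humidity follow a seasonal sinusoid peaking in mid-July plus AR(1) noise
(autocorrelation 0.7 for temperature, innovation sd 1.5 °C); wind is
lognormal; radiation has a seasonal cycle with additive noise; pressure is
Gaussian around 1013 hPa. Monthly synoptic anomalies (T 1.2 °C, RH 8%,
SR 40 W/m², V 25%, independent across zone-months) are added so that monthly
means retain variance beyond the shared seasonal cycle — without them,
30-day averaging leaves the six indices essentially rank-one. Specific
humidity is back-solved from (RH, T, p) through the humidity chain, so the
index engine's derived RH reproduces the stored one (asserted to 1e-6).

Milk responses are linear in the six *normalized* monthly indices,
`y = Zβ + ε`, with Gaussian noise calibrated as
`σ² = Var(Zβ)(1 − R²)/R²` so the generating model's population R² hits a
target: 0.5 for spring yield, 0.7 for summer yield, 0.12 for fat and
protein (mirroring the weak fat/protein fits). Coefficient presets encode
the published model equations — spring yield
`−3.58 THI − 0.77 ETI + 5.14 ESI − 2.3 RRP` (an alternative spring
parameterization with `+3.13 RRP` is also shipped; the two published spring
models disagree on the sign of RRP, which is documented rather than
resolved), summer yield `−1.6 THI − 0.28 ETI + 1.47 ESI` (and the
four-predictor variant) — plus weak fat/protein vectors and an all-zero
null. All draws derive from one seed; studies are bit-reproducible.

### What the generator does and does not establish

Collinearity among the indices is induced *naturally*, by computing all six
from the same weather, rather than by prescribing a correlation matrix. This
exercises the index code and reproduces the defining difficulty of the
analysis — but it makes the indices far more collinear than a convenient
test harness would be: THI, ESI and RRP are each approximately the same
`a·T + b·RH` factor (sensitivity ratios b/a ≈ 0.08–0.11) because their
distinguishing inputs carry negligible weight at monthly scale (ESI's solar
coefficient is 0.002; RRP's wind coefficient 0.63 m/s against a ~6.5-unit
temperature term). Measured pairwise correlations run 0.88–0.997.

Consequently *exact* support identification is a rare event here: the
four-predictor spring truth {THI, ETI, ESI, RRP} contains near-duplicate
predictors with large opposite coefficients, and the LASSO path typically
collapses them into sparser combinations. The test suite quantifies this
honestly (candidate-inclusion and final-selection rates are reported by the
acceptance script) instead of engineering an easier correlation structure.
What the generator *does* establish: predictive skill transfers
(cross-validated pooled r ≈ 0.67–0.87 across seeds for the summer preset,
centred near `√0.7 ≈ 0.84`), OLS refits on the true support are unbiased
(mean coefficient error < 0.1 normalized units over replicates), null models
stay near-null (final R² < 0.2 in ≥ 95% of replicates), and all selection,
validation and bootstrap machinery behaves to specification. Real test-day
data would additionally carry herd, lactation-stage and feeding structure
that the generator deliberately omits.

## Bootstrap

`bootstrap_stat()` resamples rows with replacement within strata
(zone-season by default in the pipeline), B = 1000 replicates, and reports
the percentile interval, whose endpoints are order statistics of the
replicates (quantile type 1). The statistic is caller-supplied because the
original description names the resampling scheme but not the statistic it
fed. Percentile coverage of a known mean at n = 100 measures ~94% at the
95% nominal level — the familiar mild undercoverage of the percentile
method, within the ±3% band the tests allow. Months are treated as
exchangeable within a stratum; temporal dependence is not modelled (a block
bootstrap would be the next refinement).

## Problem sizes and determinism

Monte-Carlo suites use 100 replicate studies for recovery rates, 50 for the
cross-validation envelope, 500 repetitions for bootstrap coverage, 200
random instances for the solver-vs-oracle comparison, and 1000 random inputs
per index for the two-implementation check — sizes at which the binomial
noise on every reported rate is well under the margins being asserted. Every
random quantity descends from an explicit integer seed; identical seeds give
bit-identical studies, paths, folds and bootstrap replicates.

## Known limitations

- Exact-support recovery under naturally induced index collinearity is rare
  (see above); the package reports rates rather than promising recovery.
- Absolute AIC values are convention-dependent; only ΔAIC and selection
  behaviour are asserted.
- The dew-point form is an approximation adopted for its saturation
  identity; sub-zero black-globe temperatures are out of domain by design.
- The generator does not emulate reanalysis grids, real Iranian climate
  normals, or herd-level variance components.
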