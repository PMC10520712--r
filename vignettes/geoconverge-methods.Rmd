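---
title: "Methods: convergence indices and spatial panel estimation in geoconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence indices and spatial panel estimation in geoconverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoconverge)
```

# Overview

`geoconverge` implements a complete regional analysis chain: a composite
public-health index built by entropy weighting, an industry-convergence
score built from coupling coordination degrees, Moran spatial diagnostics,
and maximum-likelihood spatial panel models with direct/indirect effect
decomposition. This vignette records the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic world does and
does not establish.

# Composite health index

Indicators carry a declared polarity. Standardization is linear min-max:
positive indicators map their minimum to 0 and maximum to 1; negative
indicators (mortalities) are reversed. The min/max scope defaults to
`per_year` — the cross-section of regions within each year — which is the
literal reading of the index formulas; a `pooled` scope is available because
entropy weighting is often applied to the pooled panel. A degenerate
indicator-year (max = min) maps to the constant 0.5 with a warning: any
constant is defensible there, the midpoint avoids polarity bias, and a
constant indicator subsequently receives entropy weight zero, so the choice
cannot leak into the index.

Entropy weights are computed once over the pooled set of all `N = n × T`
region-year observations, so a single weight vector applies to every year
and the index is comparable over time (time-varying weights would break that
comparability). The convention `0 · ln 0 := 0` is used exactly; an optional
`shift` argument implements the common `p + ε` variant, but it changes the
weights and is therefore opt-in, never silent. If every indicator is
constant there is no discriminating information and the method stops with an
error rather than returning arbitrary weights.

# Convergence scoring

Each industry's development level `U` is the entropy-weighted composite of
employment, fixed-asset investment and one output variable, all treated as
positive indicators and standardized over the pooled panel (so `U` is
comparable across years, which is what makes the convergence time series
meaningful). Development levels are computed **per industry separately**;
a joint weighting across both industries of a pair was considered and
rejected because it would make a pair's `U` depend on which partner it is
paired with.

The pairwise score is the two-system coupling coordination degree
`D = sqrt(C · T)` with `C = 2·sqrt(U1·U2)/(U1+U2)` (equivalently
`{U1·U2/[(U1+U2)/2]²}^{1/2}`) and `T = α·U1 + (1−α)·U2`. This is the
dominant two-system form in the coupling-coordination literature; `α`
defaults to 0.5 (no argument is made for prioritizing either subsystem) and
is exposed. `C = 0` when either subsystem is absent, and `C = 1` exactly
when `U1 = U2 > 0` (AM–GM), so `D` rewards both level and balance.

The overall convergence degree synthesizes the partner columns. The default
`entropy` method computes entropy weights **on the raw pairwise-D columns**
(already in [0, 1]) and aggregates the raw values — this keeps the
idempotence property that identical columns synthesize to the common value.
If all columns are constant the entropy weights are undefined and the method
falls back to an equal-weight mean with a warning. A plain `mean` method is
provided as a sensitivity option.

# Spatial structure and Moran diagnostics

The weight matrix is binary geographic adjacency built from an edge list; no
polygon processing is performed (real-data users supply the edge list, the
synthetic world uses a rook lattice). Islands are kept as zero rows and
reported — never silently dropped or reconnected, because graph surgery is
an analytic choice the user must make explicitly.

Moran's I is computed with the raw binary matrix exactly as the statistic is
written (it self-normalizes by the total weight); row-standardized input is
accepted for cross-checks. Inference uses the randomization-assumption
moments with a one-sided upper-tail p (the positive-autocorrelation
alternative), the common default when the assumption is unstated. No
multiple-testing correction is applied across yearly tests. The local
statistic classifies quadrants from the signs of the own deviation and the
weighted neighbour deviation, which is free of any axis-scaling convention;
zero deviations classify as "low".

# Spatial panel estimation

Models are estimated on the demeaned panel (within transformation:
individual, time, or two-way). Row standardization of W is applied before
estimation — it bounds the spatial parameter above by 1 and makes the
demeaning commute with the spatial lag, which the transformed likelihood
relies on. The admissible interval for ρ (and λ) is
`(1/ω_min, 1/ω_max)` with ω the eigenvalues of the row-standardized W, inset
by `δ = 1e-5` at each end; estimates within `1e-4` of a boundary are flagged.

The concentrated likelihood over the scalar spatial parameter uses the
eigenvalue form of the log-Jacobian, `Σ_k ln(1 − ρ ω_k)`. For SLM/SDM the
residual sum of squares is the exact quadratic
`RSS(ρ) = a0 − 2ρ a1 + ρ² a2`, so each likelihood evaluation is O(1); the
SEM refilters the design per λ (k is small at this scale). The SDM is the
SLM with the spatially lagged covariates appended to the design.

**Incidental-parameter handling.** With `bias_correct = TRUE` (default) the
likelihood is the exact transformed one: individual demeaning leaves `T − 1`
effective periods, cross-sectional demeaning leaves `n − 1` effective
regions and removes the component of W along the constant vector — so one
unit eigenvalue is dropped from the log-Jacobian and σ² is estimated over
the effective dimensions. This removes the classic downward bias in σ̂² (and
with it, undercoverage of Wald intervals). The same mathematics applies to
one-way demeaning, so the correction defaults on for every fixed-effects
mode, not only two-way; `bias_correct = FALSE` reproduces the naive
convention for comparison.

The parameter covariance is the inverse of the analytic expected information
matrix (with the trace terms evaluated on the projected spatial operator
when time effects are demeaned); the test suite cross-checks it against a
numerical Hessian of the full log-likelihood. Two R² conventions are
reported because the convention is often unstated: `r2_naive` (squared
correlation of raw fitted values, fixed effects included) and `r2_within`
(on the demeaned scale).

**Identification caveat.** For data generated with ρ = 0 and θ = 0, the SDM
likelihood has a common-factor ridge: any ρ with θ = −ρβ fits noiseless data
identically, so ρ̂ has finite-sample spread no matter how small the noise.
The reduction tests therefore assert the identities that are exact — β
recovery, the ridge relation, and the SLM's sharply identified ρ̂ ≈ 0 —
rather than a pointwise ρ̂ = 0 for the SDM.

**Specification tests.** LR tests compare nested fits
(`2Δloglik`, clipped at zero, chi-square reference); SDM-vs-SEM is treated
with k restrictions as is conventional in this literature. The Hausman
comparator is the non-spatial error-components random-effects model
estimated by feasible GLS (within/between variance components,
quasi-demeaning); a spatial-lag RE variant is deliberately out of scope —
the Hausman step functions as a model-selection device, and the non-spatial
FGLS-RE is the standard comparator for it. A non-positive-definite variance
difference falls back to a pseudo-inverse with a warning.

**Log transformation** applies the natural log to all model variables and
refuses non-positive values with the offending cell named. A min-max index
can legitimately hit exactly 0 (the worst region-year); the package does not
shift silently — rescale the index (e.g. affinely into `[ε, 1]`) before a
log-scale fit, and report having done so.

# Effect decomposition

Direct/indirect/total effects are the averaged diagonal / off-diagonal row
sums / full row sums of `S_r(W) = (I − ρW)^{-1}(I β_r + W θ_r)`, computed by
dense solve (the package targets n ≤ 200). Total = direct + indirect holds
to machine precision by construction. Inference simulates
`(β, θ, ρ)` from the asymptotic normal with the fit's covariance (1,000
draws by default, seeded; draws with ρ outside the admissible interval are
rejected), and reports the draw standard deviation, `t = point/SE` and
two-sided normal p — the standard simulation approach for spatial effect
decompositions; a delta-method alternative is not implemented. Regional
heterogeneity refits the model per regional subset with the re-standardized
principal submatrix of W; a subset that develops islands aborts with a
message naming it, leaving other subsets intact.

# The synthetic world

The generator emulates the scale of the study it is designed around: a
30-region rook lattice (5 × 6, grouped into east/central/west column bands)
observed over 18 years. Its defaults are the published magnitudes: spatial
parameter 0.239, convergence coefficient 0.576 with the accompanying control
and spatial-lag coefficients, covariate level moments matched to the
published descriptive table (aging 9.59 ± 2.14 %, education 8.68 ± 1.04
years, real per-capita GDP 28,797 ± 24,461, urbanization 52.3 ± 14.7 %,
government health share 5.44 ± 1.98 %), health indicators bracketed to the
published ranges (life expectancy [65, 85] years, perinatal mortality
[1.8, 25] per thousand, maternal mortality [1, 161] per 100,000).
Unstated values were chosen once as plausible for such a panel and not
revisited: innovation variance σ² = 0.01 (≈10% outcome dispersion on the
log scale), fixed-effect dispersions 0.1 (regional) and 0.05 (yearly),
covariates drawn i.i.d. normal on the log scale with a mild spatial
moving-average component (φ = 0.5) mirroring the geographic clustering of
provincial socio-economics, and industry tables driven by a latent
per-region scale (log-sd 0.6) with input growth rates of 4–10% per year so
the derived convergence degrees span roughly 0.1–0.65, the published range.

The outcome is generated by exact linear solve of
`(I − ρW) y_t = X_t β + W X_t θ + μ + v_t 1 + ε_t` each year — no series
truncation — with ln(HICD) taken from the convergence stage computed on the
simulated industry tables, so the pipeline's estimates can be compared
against known truth end to end.

What the synthetic world does **not** emulate: the true inter-variable
correlations of any real provincial panel, missing data (the generator
produces none), and the observed yearly Moran trajectory of a real outcome —
with the published coefficient magnitudes and weakly clustered covariates,
the simulated outcome's yearly Moran statistics hover near zero rather than
at the strongly positive values a real health surface shows. A green test
therefore establishes the correctness of the algorithms and their
calibration under a known process, not the reproduction of any published
coefficient table; the original tables come from restricted yearbook data
that are not redistributable.

# Numerical choices and limitations

- Scalar likelihoods are maximized with Brent search at tolerance
  `√machine-eps`; the optimum is verified against a fine grid in the tests.
- Eigenvalues of the row-standardized W are obtained from the general dense
  solver and validated to be numerically real (the matrix is similar to a
  symmetric one); a genuinely complex spectrum is an error.
- Covariance matrices are symmetrized and eigenvalue-clipped at zero when a
  repair is needed, always with a warning.
- Dense linear algebra throughout: the intended scale is tens of regions,
  not thousands.
- Not implemented: GMM/IV spatial estimators, dynamic spatial panels,
  higher-order lags, Geary's C / Getis–Ord statistics, inverse-distance or
  economic weight matrices, figure rendering.
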