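# geoconverge

Spatial panel econometrics for studying how the convergence of a focal
healthcare industry with its partner industries relates to regional
public-health performance. The package is aimed at health economists and
spatial epidemiologists working with province-level (or any region-by-year)
balanced panels, and ships a synthetic-data generator with a known
data-generating process so the whole pipeline is testable without restricted
yearbook data.

## What it computes

**Composite health index.** Three indicators — life expectancy at birth
(positive), perinatal mortality and maternal mortality (negative) — are
min-max standardized per year with polarity,

    p_it = (y_it - min_t y) / (max_t y - min_t y)        (positive)
    p'_it = (max_t y - y_it) / (max_t y - min_t y)       (negative)

and aggregated with entropy weights `w_j ∝ 1 - e_j`, where
`e_j = -(1/ln N) Σ_i q_ij ln q_ij` is the normalized Shannon entropy of the
indicator's cross-observation proportions, giving
`Health_it = Σ_j w_j p_itj ∈ [0, 1]`.

**Industry convergence.** Each industry's development level `U ∈ [0, 1]` is
an entropy-weighted composite of employment, fixed-asset investment and
output. Pairwise convergence between the focal industry H0 and partner Hk is
the coupling coordination degree

    C = 2 sqrt(U1 U2) / (U1 + U2),   T = α U1 + (1-α) U2,   D = sqrt(C T),

and the per-region-year degrees against the 12 partners are synthesized
(entropy-weighted by default) into one overall convergence degree (HICD).

**Spatial diagnostics.** Global Moran's I
`I = Σ_ij w_ij (x_i - x̄)(x_j - x̄) / (S² Σ_ij w_ij)` with
randomization-assumption z/p inference per year, and local Moran's I with
HH/LH/LL/HL quadrant classification, on a binary adjacency matrix W.

**Spatial panel models.** Non-spatial FE, spatial lag (SLM), spatial error
(SEM) and spatial Durbin (SDM) panel models with individual/time/two-way
fixed effects, estimated by concentrated maximum likelihood on the demeaned
panel; the log-Jacobian `ln|I - ρW|` is computed from the eigenvalues of the
row-standardized W. Likelihood-ratio tests (SDM vs SLM/SEM, fixed effects)
and a Hausman FE-vs-RE test support specification choice. SDM/SLM fits are
decomposed into direct, indirect (spillover) and total effects via
`S_r(W) = (I - ρW)^{-1}(I β_r + W θ_r)`, with Monte-Carlo standard errors,
nationally and for east/central/west regional subsets.

## Worked example

```r
library(geoconverge)
config <- study_config(seed = 42)   # 30-region lattice, 18 years, known SDM truth
report <- run_study(config)
report$fits$SDM
```

```
SDM panel model (twoway effects, log scale), n = 30, T = 18
   term estimate     se      t         p
   HICD   0.5142 0.0712   7.23  5.01e-13
    Age  -0.5045 0.0220 -22.90 4.51e-116
    ...
    rho   0.2714 0.0470   5.77  7.72e-09
sigma2 = 0.01009, log-likelihood = 432.7590, R2 (naive) = 0.9467, R2 (within) = 0.8778
```

The generator's truth here is `rho = 0.239` and a convergence coefficient of
`0.576`; the fit recovers both within sampling error (the HICD estimate
0.514 ± 0.071 covers 0.576, and 0.271 ± 0.047 covers 0.239). Decomposing:

```r
report$effects_national[, c("term", "direct", "direct_t", "indirect", "indirect_t")]
#>   term direct direct_t indirect indirect_t
#> 1 HICD  0.514      6.8 -0.00528    -0.0274
#> 2  Age -0.482    -22.8  0.33227     6.4408
#> ...
```

so the convergence degree has a strong positive direct effect on the health
outcome and no significant spillover — the spatial-lag coefficient on HICD
is small and insignificant, while its direct effect is precise. Model
selection mirrors the usual workflow:

```r
report$tests
#>            name statistic df         p
#>   LR_SDM_vs_SLM     311.4  6 2.94e-64   # SDM preferred over SLM
#>   LR_SDM_vs_SEM     294.8  6 1.09e-60   # ... and over SEM
#>   LR_SDM_effects_twoway_vs_none  336.7 46 7.3e-46
#>         Hausman      10.1  6 0.120
```

`write_study_report(report, "out/")` writes all tables (descriptives, yearly
Moran, model comparison, national and regional effects, convergence tables)
as deterministic CSVs plus a `metadata.json` run record. A thin CLI wrapper
lives at `inst/scripts/geoconverge-run.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete synthetic study (index construction, convergence
scoring, Moran diagnostics, all four model fits, specification tests, and
national plus regional effect decompositions) from scratch under the given
seed, writes the study tables next to the output file, and emits the JSON
target report.
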