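# fertdiff

Forecasting education-specific completed cohort fertility with
education-specific diffusion rates.

## What this solves, and for whom

Multistate population projections (the kind feeding human-capital and
climate-adaptation scenarios) need fertility assumptions *per education
group*, but education-stratified fertility time series are scarce, so those
assumptions are usually back-derived from overall-fertility forecasts.
`fertdiff` is for demographers who instead want to forecast
education-specific fertility directly, in settings — Sub-Saharan Africa
foremost — where fertility is still in transition and the education
environment is improving fast.

The pipeline:

1. **Cohort conversion.** Education-age-specific period fertility rates on a
   5-year grid are summed along cohort diagonals into completed cohort
   fertility: `CFR(t,e) = 5 * Σ ASFR(i, e, t+i)` over age groups
   `i = 15, 20, …, 40` (ages 45–49 are never summed). Cohort measures avoid
   the tempo distortions that make period fertility jumpy.
2. **Lee–Carter completion.** Cohorts truncated by the end of the observed
   window (typically 1980–1984 and 1985–1989) are completed by fitting
   `log m(x,t) = a_x + b_x k_t` per (country, education), continuing `k_t`
   by random walk with drift, and summing the mixed observed/extrapolated
   diagonal.
3. **Diffusion rates.** The estimand: the fractional change in CFR per
   one-year gain in Skills-in-Literacy-Adjusted Mean Years of Schooling
   (SLAMYS) between reference cohorts,
   `r_e = (CFR_e(1985) − CFR_e(1955)) / CFR_e(1955) / ΔSLAMYS` — negative
   when fertility falls as schooling rises.
4. **Projection.** `CFR_e(t+5) = CFR_e(t) · (1 + r_e · ΔSLAMYS)`, iterated
   along a projected SLAMYS path; Africa-wide rates combine with
   country-specific SLAMYS. Education-weighted aggregation gives the overall
   cohort fertility trend, and an out-of-sample protocol scores the method on
   held-back cohorts.
5. **Strata Poisson model.** The cross-sectional evidence for the diffusion
   reading: ideal family size (and children ever born at ages 40–49) from
   DHS-like microdata regressed on own education, stratum mean schooling and
   their interaction, with fixed or random stratum effects, producing
   education-specific prediction curves over stratum schooling.

Every input has a seeded generator with known parameters, so the whole
pipeline is testable end to end without external data.

## Worked example

```r
library(fertdiff)

sc      <- demo_scenario(noise_sd = 0, seed = 1)   # Africa-like conditions
surface <- generate_surface(sc)
slamys  <- generate_slamys("AFRICA", sc$slamys_start, sc$slamys_path,
                           cohorts = sc$cohorts)

cfr <- convert_all(surface, seq(1955, 1985, by = 5))
head(cfr, 4)
#> # A tibble: 4 × 5
#>   country cohort education   cfr status
#>   <chr>    <dbl> <chr>     <dbl> <chr>
#> 1 AFRICA    1955 higher      5.2 observed
#> 2 AFRICA    1955 none        7.2 observed
#> 3 AFRICA    1955 primary     6.8 observed
#> 4 AFRICA    1955 secondary   6   observed

estimate_all_rates(cfr, slamys, 1955, 1985, region = "AFRICA")
#> # A tibble: 4 × 2
#>   education   rate
#>   <chr>      <dbl>
#> 1 none      -0.102
#> 2 primary   -0.111
#> 3 secondary -0.116
#> 4 higher    -0.116
```

The rates read as: each one-year gain in SLAMYS between the 1955–1959 and
1985–1989 cohorts is associated with a 10.2% (no education) to 11.64%
(higher education) drop in completed cohort fertility.

Hold-out validation — estimate on cohorts 1955–1965 only, project 1970–1985,
score against the held-back rows:

```r
weights <- generate_weights("AFRICA", seq(1955, 1985, 5),
                            interpolate_shares(c(0.7, 0.2, 0.08, 0.02),
                                               c(0.25, 0.3, 0.3, 0.15), 7))
out_of_sample(cfr, slamys, weights, truncation_cohort = 1965,
              horizon_cohort = 1985)
#> Out-of-sample validation: AFRICA | estimation through 1965 | projected to 1985
#> Estimated diffusion rates (fraction per SLAMYS year):
#>  education       rate
#>       none -0.1146401
#>    primary -0.1261430
#>  secondary -0.1324746
#>     higher -0.1334057
#> Held-out error summary (MAPE in percent):
#>  education      mape       rmse
#>     higher 0.6425986 0.02508611
#>       none 0.4643083 0.02654375
#>    primary 0.5696785 0.02972345
#>  secondary 0.6329676 0.02859176
#>  aggregate 0.5532989 0.02780562
```

Even on noise-free data the short-window rates differ slightly from the
full-window ones (the endpoint estimator compounds across cohort steps), yet
held-out fertility is predicted to within two-thirds of a percent for every
education group — the sub-percent MAPE here is the signature of data that
follow the projection recurrence closely.

The strata-level Poisson model:

```r
md  <- generate_microdata(n_strata = 50, women_per_stratum = 1000, seed = 1)
fit <- fit_ifs_model(md, outcome = "ideal_family_size", mode = "fixed")
predict_curves(fit, seq(0, 12, by = 0.5), "secondary")
```

gives declining predicted family-size curves in stratum schooling for every
attainment group.

## Command line

A thin CLI over the same functions lives at `inst/cli/fertdiff.R`:

```sh
Rscript inst/cli/fertdiff.R simulate --config run.yaml
Rscript inst/cli/fertdiff.R convert  --config run.yaml
Rscript inst/cli/fertdiff.R estimate --config run.yaml
```

Subcommands: `simulate`, `convert`, `complete`, `estimate`, `project`,
`validate`, `strata-fit`; the YAML config carries paths, cohort windows,
estimation endpoints and the seed (see `load_config()` for defaults).

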