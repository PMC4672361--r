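# pahrisk

Probabilistic human-health risk assessment of polycyclic aromatic
hydrocarbons (PAHs) in drinking water, for environmental-health scientists
analysing village-scale monitoring campaigns: multi-analyte PAH profiles
are collapsed to benzo[a]pyrene-equivalent (BaPeq) concentrations, screened
against national drinking-water standards, and propagated through the US
EPA two-route exposure model to lifetime cancer risks — deterministically
and by Monte Carlo simulation with rank-correlation sensitivity analysis.
A synthetic-campaign generator emulating a two-season, three-water-type,
two-group (risk vs control village) study design makes the whole pipeline
runnable and testable without any external data.

## The model

BaPeq weighting over the seven carcinogenic PAHs (PEFs: BaA 0.1, Chy
0.001, BaP 1, BbF 0.1, BkF 0.01, DahA 1, IcdP 0.1):

    BaPeq = sum_i PEF_i * C_i

Chronic daily intakes (mg/kg/day) for ingestion and dermal contact, with
Cw in mg/L:

    CDI_ingestion = Cw * IR * EF * ED / (BW * AT)
    CDI_dermal    = Cw * SA * Kp * ET * EF * ED * CF / (BW * AT)

Lifetime cancer risk per route is `CR = CDI * SF`; the ingestion route
uses the oral slope factor (7.3 (mg/kg/day)^-1), the dermal route the
absorbed-dose factor `SF/AAF = 7.3/0.92 = 7.9`. Total risk is the exact sum
of the routes, classified against the 1e-6 / 1e-4 risk-management range.
The Monte Carlo engine fits the water-concentration distribution to the
detected BaPeq values (ML + AIC over lognormal/gamma/Weibull/normal),
draws all uncertain inputs (lognormal BW/ET/IR/SA, uniform 0–70 y exposure
duration), and reports mean, SE, P5/P50/P95 and Spearman sensitivity
coefficients.

## Worked example

```r
library(pahrisk)

# Deterministic risk at the Chinese BaP drinking-water limit (10 ng/L)
total_risk(exposure_parameters(cw_ng_l = 10))
#> # A tibble: 1 × 6
#>   cdi_ingestion  cdi_dermal cr_ingestion  cr_dermal   cr_total category
#>           <dbl>       <dbl>        <dbl>      <dbl>      <dbl> <fct>
#> 1   0.000000369 0.000000445   0.00000269 0.00000353 0.00000622 acceptable
```

A CDI of 3.69e-7 mg/kg/day from ingestion plus 4.45e-7 from dermal contact
gives a total lifetime risk of 6.2e-6 — above the 1e-6 de minimis level but
well inside the acceptable range (below 1e-4).

```r
res <- run_pipeline(default_config(seed = 1))

res$exceedance[res$exceedance$standard == "china", ]
#>   standard limit n_exceed n_total percent
#> 1 china    bap         57     224    25.4
#> 2 china    total       53     224    23.7
#> 3 china    bapeq       78     224    34.8

res$mc
#> Monte Carlo risk simulation (n = 10000)
#>   mean 3.219e-06  SE 3.982e-08
#>   P5 1.683e-07  P50 1.990e-06  P95 1.041e-05
#>   sensitivity (Spearman rho):
#>     ed       +0.665
#>     cw_ng_l  +0.630
#>     bw       -0.175
#>     ...
```

On this synthetic campaign (224 realized samples from 40 villages),
25.4% of samples exceed the 10 ng/L BaP limit — and necessarily more
(34.8%) when the toxicity-weighted BaPeq is screened against the same
limit. The probabilistic risk distribution is right-skewed (mean above
median) with its 95th percentile near 1e-5, and water concentration and
exposure duration dominate the sensitivity ranking while body weight acts
protectively (negative coefficient). `res$season_table` and
`res$group_table` hold the 18-row geometric-mean comparison tables, and
`res$incidence_correlation` the incidence–mortality correlation across
villages (r = 0.84 on this seed, target 0.78).

Configuration is a YAML file mirroring `default_config()`; see
`inst/extdata/example_config.yaml`. User CSVs can replace the synthetic
stage via the `io:` block.

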