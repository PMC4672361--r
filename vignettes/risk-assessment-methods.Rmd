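---
title: "Methods: probabilistic carcinogenic risk assessment of PAHs in drinking water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic carcinogenic risk assessment of PAHs in drinking water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem

Rural populations that draw drinking water from surface water or shallow
wells can be chronically exposed to polycyclic aromatic hydrocarbons
(PAHs). `pahrisk` implements the standard four-step human-health risk
assessment for this setting — hazard identification via the 16 US-EPA
priority PAHs, exposure assessment through ingestion and dermal contact,
toxicity via the benzo[a]pyrene (BaP) slope factor, and risk
characterization against the 10^-6^–10^-4^ lifetime-risk management range —
together with the descriptive statistics used in two-group (high-rate
"risk" villages vs "control" villages) ecological comparisons.

Because village-level monitoring data of this kind are rarely deposited,
the package ships a first-class synthetic-data generator that reproduces
the statistical structure such campaigns exhibit, so every downstream stage
is fully testable without any external download.

## BaPeq weighting and screening

Carcinogenic potency differs by orders of magnitude across the PAH class,
so multi-analyte profiles are collapsed to a BaP-equivalent concentration

$$\mathrm{BaPeq} = \sum_{i \in \mathcal{C}} \mathrm{PEF}_i \, C_i,$$

where $\mathcal{C}$ is the seven-analyte carcinogenic subset (BaA, Chy,
BaP, BbF, BkF, DahA, IcdP) and the potency equivalency factors are the US
EPA (1993) relative potencies (BaA 0.1, Chy 0.001, BaP 1, BbF 0.1,
BkF 0.01, DahA 1, IcdP 0.1). The table is overridable via
`default_pef_table()`.

Non-detects contribute to sums according to a configurable policy:
`zero` (default for sums and screening), `half_dl`, or `dl`. `zero` is the
conservative-on-detection choice that keeps an analyte never detected from
inflating BaPeq; `half_dl` is the default wherever a geometric mean is
taken, because a zero substitution is undefined on the log scale. The
policies are provably ordered (`zero <= half_dl <= dl` for every sample),
and the property suite asserts this.

Screening compares each sample against named standards (China: BaP
10 ng/L, total PAHs 2000 ng/L; US: BaP 200 ng/L; Egypt: BaP 700 ng/L) with
a strict `>` comparison — a concentration exactly at a "must be less than"
limit is counted compliant. The Chinese BaP limit is additionally applied
to BaPeq (`bapeq_ng_l: 10`), making explicit the convention of screening
the toxicity-weighted sum against the index-compound limit; because
`PEF(BaP) = 1`, the BaPeq exceedance rate can never fall below the BaP
exceedance rate.

## Exposure and risk model

Chronic daily intakes (mg/kg/day, lifetime-averaged) follow the US EPA
two-route model:

$$\mathrm{CDI_i} = \frac{C_w \cdot IR \cdot EF \cdot ED}{BW \cdot AT},
\qquad
\mathrm{CDI_d} = \frac{C_w \cdot SA \cdot K_p \cdot ET \cdot EF \cdot ED
\cdot CF}{BW \cdot AT},$$

with $C_w$ the BaPeq concentration in mg/L (the package interface takes
ng/L and applies the 10^-6^ conversion exactly once, at the dose-equation
boundary) and $CF = 0.001$ L/cm^3^. Lifetime risk per route is the linear
low-dose extrapolation $CR = CDI \times SF$; the total is the exact sum of
the two routes.

Point defaults (adult, rural eastern-Chinese exposure factors): IR
2.39 L/day, EF 350 days/year, ED 70 years, BW 62.1 kg, AT 25,550 days
(70 y x 365 d), SA 16,000 cm^2^, Kp 1.2 cm/h, ET 0.15 h/day, oral SF 7.3
(mg/kg/day)^-1^. The dermal route uses the absorbed-dose slope factor
$SF_{oral}/AAF$ with $AAF = 0.92$ (the gastrointestinal absorption fraction
underlying the oral factor), i.e. 7.93; reports round this to 7.9, but
computation keeps full precision (a `rounded_dermal_sf` switch reproduces
the rounded convention exactly when strict replication of published
arithmetic is wanted). The single $K_p$ for BaP is applied to BaPeq as a
whole — a simplification that slightly misweights the dermal contribution
of the non-BaP carcinogens and is a known limitation of the index-compound
approach.

The deterministic analysis fixes ED at 70 years (the conservative
whole-lifetime assumption); the probabilistic analysis treats ED as
uniform on 0–70.

## Monte Carlo uncertainty propagation

`simulate_risk()` draws all uncertain inputs independently, evaluates the
deterministic model on every row of the draw table, and summarizes with
the mean, the standard error of the mean, and the empirical 5th/50th/95th
percentiles (type-7 linear interpolation — the R default, fixed so that
tests are convention-stable). Input families:

* $C_w$: fitted to the detected BaPeq values by `fit_cw_distribution()`,
  which maximum-likelihood-fits each candidate family (lognormal, gamma,
  Weibull, normal), selects by lowest AIC and breaks ties by the smaller
  Kolmogorov–Smirnov statistic. Environmental concentrations almost always
  select lognormal; the other families keep the selection honest.
* BW, ET, IR, SA: lognormal with means at the point values. Their spreads
  are not identifiable from published summaries, so they ship as
  configurable coefficients of variation (0.2 each, a typical
  anthropometric/behavioural CV). No acceptance-level conclusion depends
  on these defaults — only on orderings and degenerate limits.
* ED: uniform(0, 70) years. Zero is included; a zero-duration draw yields
  zero risk and is a legal output, not an error.

Parameters are sampled independently (no correlation structure is
imposed), and the draw count defaults to n = 10,000.

Sensitivity is reported as the Spearman rank correlation between each
varied input and the output risk — the "rank order correlation" convention
of spreadsheet risk tools. Constant inputs are reported `NA`. Two useful
analytic facts guide interpretation: on the rank scale the model is
effectively $\log CR = \log C_w + \log ED - \log BW + \text{const}$, and
for $ED \sim U(0, a)$ the variance of $\log ED$ is exactly 1 regardless of
$a$. A lognormal $C_w$ therefore outranks ED precisely when its log-scale
SD exceeds 1 (GSD above $e \approx 2.7$). The sensitivity-ordering checks
in the test suite use GSD 4 (log-SD 1.39), which satisfies the
"concentration dominates" premise with a clear margin and yields
coefficients near 0.8 for $C_w$ and 0.55 for ED at n = 10,000.

Two invariants pin the engine to the deterministic oracle: collapsing all
distributions to points reproduces `total_risk()` to machine precision
with SE exactly 0, and with only $C_w$ varied the Monte Carlo mean matches
the closed-form $CR(E[C_w])$ (linearity) within Monte Carlo error.
Because $E[C_w] > \mathrm{median}(C_w)$ for a lognormal and the model is
linear, the probabilistic mean always sits above the deterministic risk
evaluated at median parameters — the expected "higher than but consistent"
relation between the two approaches.

## Group statistics

Concentration summaries are geometric means with 95% confidence intervals
from the t-interval on logs. Comparisons follow the nonparametric
convention for skewed environmental data: Wilcoxon rank-sum for two
groups, Kruskal–Wallis for three, with ANOVA available for
Box-Cox-transformed values. `boxcox_lambda()` profiles the Box-Cox
log-likelihood on a fixed grid (-3 to 3, step 0.01) — deliberately a
transparent grid search rather than a numeric optimizer, so the chosen
lambda is reproducible to the grid resolution; the test suite
cross-checks it against `MASS::boxcox`. Normality is assessed with the
Anderson–Darling and Lilliefors-corrected Kolmogorov–Smirnov tests.

P-values are uncorrected across the many analyte-by-stratum cells, the
convention of monitoring reports where each cell is read descriptively;
users who want family-wise control can apply `p.adjust` to any table
column. The rank test supplies the headline P value in the rendered
tables (the ANOVA-on-transformed-values route is available but secondary,
since rank tests are exact under the null regardless of the achieved
normality).

`summary_table()` renders the standard campaign layout: one row per
detected analyte plus total PAHs, carcinogenic PAHs and BaPeq (18 rows in
the default campaign, where one analyte is never detected and is omitted
because its geometric mean would be pure substitution), GM (95% CI) per
season-by-water-type or group-by-water-type stratum, and P columns across
and within strata.

## The synthetic campaign generator

The generator emulates a two-season (winter/summer), three-water-type
(surface SW, shallow groundwater SG, deep groundwater DG), 40-village
(20 risk + 20 control) design, with one pooled record per village x water
type x season cell and uniform random cell missingness (default rate
8/240, so a full factorial of 240 thins to about 232 realized samples —
the generator does not model which specific cells go missing, since that
is unknowable in general).

**Concentrations** follow an additive lognormal model per analyte:
baseline + summer shift + water-type effect + village random intercept +
residual. The cell means are calibrated by method of moments on logs to a
built-in season-by-water-type geometric-mean matrix representative of
PAH-impacted village water sources (naphthalene dominant, summer well
above winter, SW > SG > DG, BaP geometric means of 3–12 ng/L). Log-scale
spreads are not derivable from a GM matrix, so they are fixed design
choices: between-village SD 0.4 and residual SD 0.7 (total ~0.8,
consistent with the GSD 2–3 that typical concentration CIs imply). The
village intercept is shared across analytes, encoding that contamination
is a property of the local source. DahA is generated at a 0.1 ng/L
geometric mean so that it is always censored at the 1–5 ng/L detection
limits — an analyte that is never detected, which also exercises the
all-censored code paths (row omitted from GM tables, zero contribution to
sums under the default policy).

**Detection limits** default to 1 ng/L, with naphthalene and DahA at
5 ng/L. Censoring flags any value strictly below the limit and removes the
number; raising a limit can only create non-detects, never remove them.

**Cancer registries** draw incidence and mortality from a Gaussian copula
on log rates: within each group the marginals are lognormal,
moment-matched to the group means/SDs (risk incidence 397.47, SD 92.35;
control 134.89, SD 50.33; mortality 313.44/73.83 and 140.06/71.73, all per
100,000/yr). The latent normal correlation is solved analytically (bivariate
lognormal mixture moments + `uniroot`) so that the *pooled* natural-scale
Pearson correlation across both groups equals the target (default 0.78).
This matters: with this much between-group separation, naively setting the
within-group correlation to 0.78 would inflate the pooled correlation to
about 0.9, because the group contrast itself carries covariance.

**What the generator does not emulate:** spatial structure, age/sex
demography, temporal autocorrelation beyond the two seasons, correlated
analyte-specific village effects, and any causal link between water
concentrations and the cancer rates (the two are generated independently,
matching the ecological-study reading that the water exposure does not
explain the group contrast). Tests passing on synthetic campaigns
therefore validate the pipeline's arithmetic and statistical conventions,
not any claim about real monitoring data.

## Numerical and design choices

* All randomness in a campaign flows from one integer seed; the sample
  stage and the Monte Carlo stage use fixed offsets of it so the streams
  are independent but jointly reproducible. A run is a pure function of
  (input files, config), and the manifest records a hash of the config.
* Problem sizes used in the validation suite: campaigns of 40 villages
  (~232 samples), Monte Carlo at n = 10,000, parameter-recovery checks at
  5,000–10,000 draws or villages. These sizes make stochastic checks
  stable at the tolerances asserted while keeping the whole suite fast.
* Degenerate inputs are first-class: constant vectors are rejected (or
  reported `NA`) with informative messages in distribution fitting,
  sensitivity analysis and normality testing; a point-collapsed Monte
  Carlo run is legal and exactly reproduces the deterministic result.
* Risk classification uses strict inequalities at 10^-6^ and 10^-4^, so a
  risk exactly at a threshold falls in the lower category.
* Known limitations: left-censoring is handled by substitution rather
  than censored-likelihood estimation (adequate at the low non-detect
  rates the default campaign produces, less so for heavily censored
  analytes); the dermal model uses the BaP permeability for the whole
  BaPeq mixture; exposure is not age-stratified.
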