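---
title: "Methods: panel estimation and forecast validation of smoking-related healthcare expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel estimation and forecast validation of smoking-related healthcare expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokecast)
```

## The model and its assumptions

`smokecast` estimates a single-equation reduced-form autoregression for the
natural logarithm of real per-capita state healthcare expenditure. All
explanatory variables enter as one-year-lagged natural logarithms, so every
slope is an elasticity. Five kinds of terms appear:

1. **State-specific time-varying variables** — adult current smoking
   prevalence (%), real per-capita income, percent elderly, percent
   African-American, percent Hispanic.
2. **Mean cigarette consumption per adult current smoker** (packs/year),
   treated as mismeasured: it is constructed as taxed sales over
   (prevalence x adult population), and untaxed cross-border purchases tied
   to interstate tax differentials contaminate it. Its elasticity is
   therefore estimated by instrumental variables.
3. **Region-specific real cigarette tax terms** — one elasticity per BEA
   Economic Region, absorbing the systematic part of the tax-differential
   measurement error.
4. **Lagged cross-sectional national averages**, equally weighted by state,
   of the state variables and of expenditure itself. These control for
   common national trends, measured or not, that would otherwise confound
   the within-state estimates. Which averages to include is not decided a
   priori but by out-of-sample forecast performance.
5. **State fixed effects**, absorbing everything time-invariant.

The model assumes elasticities homogeneous across regions (testable with
`fit_regional()`), a one-year lag (an approximation that mixes the
error-correction adjustment toward the long-run cointegrating relation with
genuinely short-run responses), and a stationary AR(1)-like error around
the cointegrating relation.

## Estimation conventions

`fe2sls()` is the within (fixed-effects) two-stage least-squares estimator.
Conventions that change numbers, and the choices made:

- **Instruments.** Prevalence lagged two and three years and consumption
  lagged three years; all instrument lags must be strictly deeper than the
  regression lag. The first stage regresses the within-transformed
  endogenous column on the instruments plus all exogenous columns.
- **Residuals and sigma.** Second-stage residuals are computed with the
  *original* (not fitted) endogenous column — the standard 2SLS convention —
  and `sigma` divides by `N - K - G` (slopes plus absorbed fixed effects).
- **Cluster-robust covariance.** Sandwich over states with small-sample
  factor `G/(G-1) x (N-1)/(N-K)`. The source analysis does not state its
  correction; this matches common panel software, and with one observation
  per cluster it reduces exactly to the HC1 heteroskedasticity-robust
  estimator (a test pins this equivalence against the `sandwich` package).
- **Confidence intervals.** Normal (z) critical values, not t: the printed
  intervals of the published elasticities reproduce exactly with 1.96
  (e.g. `0.104 - 1.96 x 0.0323 = 0.0407`), which `ci_normal()` freezes as
  the convention.
- **Absorbed columns.** A column constant within every fixed-effect group
  cannot be estimated; it is reported as absorbed and excluded from the
  slope vector, never silently dropped.
- **R-squared statistics.** `panel_r2()` returns within/between/total as
  squared correlations between the linear score and the response at the
  relevant aggregation, `rho` as the fixed-effect share of error variance
  `sd(alpha)^2 / (sd(alpha)^2 + sigma^2)`, and the correlation between
  intercepts and state-mean scores.

### Regional heterogeneity

`fit_regional()` interacts chosen regressors with region indicators and
tests homogeneity by an F statistic from restricted and unrestricted sums
of squared residuals. Both models are evaluated on one shared instrument
projection (region-interacted instruments), which makes the pooled model an
exact linear restriction of the regional one, so the nesting inequality
`SSR_regional <= SSR_pooled` holds by construction rather than by luck. The
sequential grouping rule — the paper says only that sequential tests were
used — merges the pair of regions with the largest merge p-value, refits,
and repeats while that p-value exceeds 5%.

## Cointegration and instrument diagnostics

Residual stationarity is tested per state with a Phillips-Perron Z-tau
statistic (constant, Newey-West long-run variance, truncation
`floor(4 (T/100)^{2/9})` by default) and combined across states by Fisher's
`-2 sum log p` against chi-square with `2 x n_states` degrees of freedom.

A numerical choice worth flagging: the standard MacKinnon asymptotic
p-values are *liberal* at the panel's short per-state length (about 6.8%
size per state at T near 20), and the Fisher combination compounds 51 such
tests into a badly oversized panel test (about 25%). The default therefore
calibrates per-state p-values against a simulated finite-sample random-walk
null at the observed series length (2,000 replications, fixed internal
seed), which restores the panel test's size to about 5-6% with essentially
full power against stationary residuals; `p_method = "asymptotic"` retains
the textbook approximation.

Instrument validity is summarised by an Anderson canonical-correlation LM
statistic for underidentification, the cluster-robust first-stage F on the
excluded instruments classified against the standard tabulated 2SLS
relative-bias thresholds (13.91 / 9.08 / 6.46 / 5.39 for three instruments
and one endogenous regressor), and the Sargan `N x R^2` overidentification
J with `#instruments - #endogenous` degrees of freedom (inapplicable when
just-identified). Residual serial correlation is reported as per-state
lag-1 autocorrelations computed *without* re-demeaning, because
fixed-effects residuals are exactly mean zero within state; this halves the
short-sample downward bias of the usual sample ACF.

## Out-of-sample forecast validation

`recursive_fit()` re-estimates on expanding windows (base period through
year t), and `one_step_forecasts()` predicts each state's year t+1 from the
fit ending at t — by construction no forecast uses information dated after
its origin, and a test perturbs future years to enforce this. Accuracy is
summarised by RMSFE on the log scale, mean relative bias in percent on the
level scale (forecast minus observed over observed; the source's sign
convention is unstated), and the correlation between forecast and observed
levels. That correlation includes the cross-state variation carried by the
state intercepts, which inflates it; it is reported as defined, not
"corrected", and per-year summaries are emitted alongside the pooled ones
(pooling all cells is the default where the source is ambiguous).

Multi-step forecasts condition on the *observed* explanatory paths rather
than forecasting the regressors: several regressors carry unit roots, and
propagating them would produce uninformatively wide intervals. Level
forecasts apply the lognormal back-transformation
`exp(yhat + sigma^2 / 2)` with the regression error variance only;
parameter-estimation variance is small enough to ignore in point forecasts
and is handled properly in the scenario simulation instead.

## Specification search and the Model Confidence Set

All `2^7 = 128` subsets of the seven candidate cross-sectional averages are
enumerated and scored by one-step-ahead squared log forecast errors over a
pre-break selection window (2007-2010 by default), on an identical cell set
for every candidate (cells any candidate cannot forecast are dropped for
all — asserted as an invariant). The Model Confidence Set then iteratively
tests equal predictive ability with the range (max-t) statistic on mean
loss differentials; the null distribution comes from a moving-block
bootstrap that resamples whole target-years (block length 2 by default),
preserving the strong cross-state correlation of forecast errors within a
year. The eliminated candidate's MCS p-value is the running maximum of
elimination p-values, which makes survivor sets nested and monotone in the
level. Exact ties are indistinguishable and survive together; candidates
that fail estimation are excluded with a warning rather than assigned
infinite loss, which would distort the bootstrap variance. The final model
is the surviving candidate with the smallest mean loss, ties broken toward
fewer averages. The bootstrap replication count (5,000 default here) and
block length are exposed as arguments since the source does not report its
values.

## Bridging the 2011 survey break

The BRFSS redesign (cell-phone frame plus raking weights) shifted the
*levels* of the survey-measured series — prevalence, consumption, percent
Black, percent Hispanic — from survey year 2011 onward without changing
their time paths. Three bridges are implemented: a second state-specific
constant for post-break observations (`intercept_shift`), common post-break
slope interactions on the survey variables and their averages
(`slope_shift`), and `both`. `select_bridge()` picks the mode with the
lowest one-step RMSFE over the post-break window (2011-2014 by default,
kept disjoint from the selection window to avoid confounding the two
searches) and reports a condition number per mode, flagging the
near-collinearity that arises when post intercepts, post slopes and
averages are combined.

Because the regression's variables are lagged, the break reaches a row
through its regressor date: the post-break era of a row is indexed on
`t - lag >= 2011` by default (`break_align = "regressor"`), with the
literal observation-year indexing available as an option. A consequence is
that the post-break intercepts only become estimable once a post-break row
enters the sample; forecasts made before that fall back to the pre-break
intercept and are flagged.

Two structural facts about this contest, established on synthetic panels:
the intercept bridge reliably beats the slope bridge under a pure level
shift (the slope columns can only mimic a level shift through the
cross-state pattern of log levels), but `both` *nests* the intercept
bridge, so the two coincide up to the sampling noise of the extra slope
columns and neither dominates the other sharply — which matches the
finding that adding slope shifts "did not improve" forecasts while
destabilising the estimates.

## The synthetic-data generator

`synth_config()` defaults define the study conditions: 51 states observed
1992-2014; the structural equation above with the published 2014
elasticities as truth (prevalence 0.104, consumption 0.113, income 0.259,
elderly 0.493, Black 0.00935, Hispanic 0.0121, the eight regional tax
elasticities, and trend coefficients for the elderly/Hispanic/expenditure
averages); state constants with dispersion 0.124 (chosen so
`rho = sd^2/(sd^2 + 0.0301^2)` is about 0.94); an AR(1) error with serial
correlation 0.56 and stationary sd 0.0301.

The explanatory variables follow common national random-walk-with-drift
log trends whose innovations share a macro factor (`trend_cor = 0.6`; the
averages are highly mutually correlated in the data this emulates, which
is exactly what makes the specification search hard), with mean-reverting
state deviations (AR 0.85). Drifts are gentle declines for the smoking
variables (-2%/yr), growth for income (+2.5%/yr — the value that, through
the income elasticity and the expenditure-average feedback, reproduces the
observed within-state expenditure growth and a within R-squared near
0.93), slow growth for the demographic shares, and rising real taxes.
Prevalence and consumption innovations are correlated (0.5), which is what
makes the prevalence lags informative instruments for consumption.

Measured consumption multiplies the true value by
`exp(noise + kappa (tax - mean tax))` with classical noise sd 0.02 and
`kappa = -0.05`: high-tax states under-measure consumption, the
cross-border story, and the regional tax terms absorb the systematic part.
The 2011 break adds per-state level shifts to the survey variables
(prevalence mean +1.5pp, sd 1.2pp; consumption mean -15, sd 18 packs;
Black +0.3/0.3; Hispanic +0.4/0.5) — magnitudes on the scale of the
documented redesign effects, whose state-level prevalence impacts spanned
roughly -1 to +4 percentage points. Shifts are additive on the level
scale, as a survey-method change moves reported levels. Regions are
assigned round-robin to balance sizes, and both the latent (true) and
measured panels are returned, with a generation report whose statistics
(realized error AR(1) fitted without intercept, fixed-effect dispersion,
break-shift means) are recomputable from the emitted draws.

What the generator does **not** emulate: actual state-by-state historical
values or geography, the ACA/Medicaid expansion discontinuity, policy
covariates (Medicaid enrollment, education, poverty, unemployment), and
any feedback from expenditure to smoking behavior. Passing tests therefore
demonstrate that the estimator, search, bridging and simulation machinery
recover known structure under the assumed data-generating process — not
that the published real-data coefficient values are correct.

## Counterfactual savings

A permanent annual relative reduction `r` compounds: the log-scale effect
in forecast year t is `t x (b_prev log(1 - r_prev) + b_cons log(1 -
r_cons))`, linear in logs — the natural reading of "permanent annual
reductions", reproducing the near-linear accumulation of the published
savings table ("totaling 25%" for five 5% cuts is read as informal linear
shorthand for the compounded 22.6%). `simulate_savings()` draws the
elasticity vector from a multivariate normal centered at the estimates
with the cluster-robust covariance via its Cholesky factor (50,000 trials
by default), and reports trial means with 2.5/97.5 percentile prediction
bounds rather than normal-approximation intervals. The lognormal
error-variance correction applies identically to the factual and
counterfactual arm and cancels from the difference, so it is not
simulated. The cross-sectional prevalence-trend elasticity can be added to
the shock (`include_cs_trend`, roughly doubling the prevalence effect) but
defaults to off: that correlation reflects historical co-movement, not a
causal channel a new policy could claim.

The dollar baseline is configurable. The published per-capita values
($51 / $55 / $99 in year one) are a few percent below the closed-form
plug-in at the $9,057 national baseline (about $100.3 for the combined
scenario); the exact baseline and state weighting behind the printed table
are not stated, so the discrepancy is documented here rather than tuned
away, and `plugin_saving()` is the package's oracle for what its own
simulation must converge to.

## Numerical choices and degenerate inputs

- Absorbed-column detection at `1e-10` of the column scale; rank
  deficiency is an error naming the collinear columns.
- A singular but positive-semidefinite coefficient covariance gets a
  `1e-12`-scale diagonal ridge before the Cholesky factorization; an
  indefinite one is an error.
- Zero-variance residual series are excluded from the unit-root test with
  a flag (so diagnostics run on partial panels); series shorter than 8 are
  likewise excluded.
- Exact loss ties in the MCS survive together; `select_best` breaks
  mean-loss ties toward fewer averages.
- Missing cells are dropped listwise (the sources treat missingness as
  completely at random); cross-sectional averages use all states observed
  in a year, including the row's own state, since no exclusion is
  documented — both choices are fixed, documented conventions.
- Variables are addressed by explicit names (`black`, `hispanic`, ...)
  throughout rather than single-letter symbols; the conventional symbol
  mnemonics for the two demographic shares are swapped in parts of this
  literature, and names remove the ambiguity.

## Problem sizes used by the test suite

The suite exercises full-size panels (51 x 23) where the claim depends on
the study dimensions — parameter recovery and scenario-interval coverage
use 200 replications each, bridge selection 50, the unit-root size/power
checks 51-state panels — and smaller panels (2-24 states, 12-18 years)
for closed-form oracles, at a total runtime of about a minute. These sizes
are the package's choices for stable Monte-Carlo assertions; the
acceptance script runs one full-size pipeline with the seed supplied on
the command line.

## Known limitations

- The evidence is observational and ecological; elasticities summarise
  state aggregates, not individual risk, and the one-year lag mixes short-
  and long-run adjustment.
- The Sargan J and the homogeneity F use classical (non-cluster) forms;
  with strongly serially correlated errors their finite-sample sizes
  drift, which the tests therefore check under independent errors.
- MCS power over a four-year evaluation window is modest — with 128
  candidates most survive at 5%, exactly as the underlying procedure is
  designed to behave when the data cannot distinguish models.
- The intercept-vs-`both` bridge comparison is decided by sampling noise
  (nested models); conclusions should rest on the intercept-vs-slope
  contrast and the instability diagnostics, as discussed above.
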