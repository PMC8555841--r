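---
title: "Estimating mCPR from surveys and service statistics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mCPR from surveys and service statistics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the latent process
model, the two observation models, how the source-type variance is
estimated, the sampler, the synthetic-data generator, and the numerical and
design choices a user or reviewer should know about.

## The estimation problem

The modern contraceptive prevalence rate (mCPR) among married or in-union
women of reproductive age is measured by large national surveys run every
3–5 years. Annual monitoring therefore relies on model projections for the
years since the last survey. Routine family planning service statistics can
be converted into Estimated Modern Use (EMU), an mCPR-like annual series
that is available every year but biased in *level*: EMU counts depend on
catchment assumptions, private-sector coverage and reporting completeness,
none of which is captured by the population denominator. The empirical
regularity that motivates this package is that annual *changes* in EMU are
approximately unbiased for annual changes in mCPR, with source-dependent
noise. `fpemu` therefore treats surveys as the anchor for levels and EMU
series as evidence about recent changes.

## Process model

For a single country on an annual grid `t = 1, …, T`:

* total prevalence: `L_t = P̃ · logit⁻¹(η_t)` with asymptote `P̃ ∈ (0, 1)`;
* modern/total ratio: `R_t = logit⁻¹(ζ_t)`;
* mCPR: `ρ_t = L_t R_t`.

Both transformed states evolve by drift plus AR(1) distortion,

η_t = η_{t−1} + ω_L + ε_t, ε_t = φ_L ε_{t−1} + u_t, u_t ~ N(0, τ_L²),

with the initial distortion drawn from its stationary distribution
N(0, τ²/(1−φ²)), and the same structure (ω_R, φ_R, τ_R, asymptote 1) for
the ratio. Constant drift on the logit scale produces the logistic
prevalence transition — slow early growth, acceleration, saturation toward
the asymptote — and the distortions absorb persistent departures of
observed rates of change from that expectation. The AR(1) form for the
distortions is this package's concrete choice: published descriptions of
this model family state that time-series distortions are present without
fixing their form in the main text, and an AR(1) is the simplest stationary
process with the required persistence and identifiable parameters at
single-country scale. With `τ = 0` the model collapses exactly to logistic
growth (`η_t − η_0 = t·ω`, asserted to machine precision in the tests).

## Survey data model

A survey reports modern (`m`) and traditional (`τ`) prevalence
proportions. Writing `u = 1 − m − τ` for non-use, the observed log-ratios
`(log(m/u), log(τ/u))` are modelled as bivariate normal around the
modelled log-ratios, with diagonal covariance. Per component the variance
is

* the sampling variance mapped from the proportion scale by the delta
  method, when standard errors are recorded; plus
* a non-sampling variance by survey source, on the log-ratio scale —
  defaults 0.1 for sources labelled `DHS` and 0.2 otherwise, configurable
  in `fit_config()`. These defaults are this package's own engineering
  values, chosen to weight high-quality surveys roughly twice as strongly
  (in sd) as other sources; they are not estimates transported from any
  global model run.

Proportions of exactly zero are clamped to `0.25/ess` (effective sample
size `ess` defaulting to 1000) before the transform, since the log-ratio is
undefined at the boundary; observations with `m + τ ≥ 1` are rejected.
Decimal survey years are rounded half-up to the annual grid.

## EMU data model

For an EMU series `z_t` of source type `s` (commodities to clients,
commodities to facilities, service visits, or FP users), observations in
adjacent calendar years contribute

z_t − z_{t−1} ~ N(ρ_t − ρ_{t−1}, σ_s²).

Levels never enter, so the posterior is invariant to any constant shift of
the series — the level bias is removed by construction rather than
estimated. A series needs at least two observations to say anything about
a rate of change; shorter series are ignored with a warning. Pairs
separated by more than one year are skipped by default; a `gap_scaling`
switch instead includes a k-year gap with variance `k·σ_s²` (off by
default because the method's defining statement concerns annual changes,
and gap handling is an extrapolation).

The source-type standard deviations `σ_s` ship with defaults (clients
0.04, facilities 0.02, visits 0.03, users 0.09, proportion scale) and can
be re-estimated from data: `build_change_pairs()` assembles annual EMU
changes against an independent annual mCPR estimate series, retaining per
country only the years between the first and the most recent survey (the
period where the estimate series is survey-informed), and
`estimate_sigma()` computes the per-type root-mean-square of
`ΔEMU − ΔmCPR` with denominator `n_s` — deliberately without a
degrees-of-freedom correction, matching the estimator's definition as an
RMS of residuals around a known zero mean. A zero estimate (degenerate
input) is flagged and floored at 0.005 before use as a likelihood sd.
Residuals are pooled across countries within type; no country weighting is
applied.

Source types are identified by name everywhere. (Published tabulations of
these quantities disagree internally about which numeric index attaches to
service visits versus FP users; names remove the ambiguity.)

## Priors and inference

Default priors, all overridable via `prior_settings()`:

| parameter | prior | remark |
|---|---|---|
| `logit(P̃)` | N(1.4, 0.5²) | asymptote median ≈ 0.80 |
| `ω_L, ω_R` | N(0.05, 0.05²) | per-year logit drift |
| `φ_L, φ_R` | Uniform(0, 0.95) | distortion persistence |
| `τ_L, τ_R` | half-N(0, 0.1²) | distortion innovation sd |
| `η_0, ζ_0` | N(anchor, 1) | anchored to the earliest survey |

The anchors back-project the earliest survey's total prevalence and
modern/total ratio (through their logits, relative to the prior median
asymptote) to the grid start at the prior-mean drift. In the intended
country-specific workflow these priors stand in for information a global
hierarchical run would provide; estimating that hierarchy is out of scope
here, so the priors are explicit, configurable constants. Any parameter can
be fixed at a point value (`fixed = list(...)`), which is also how the
package's posterior-oracle test turns the model into a low-dimensional toy
that a dense grid can integrate exactly.

Sampling is adaptive random-walk Metropolis-within-Gibbs, written in C++:
one scalar Metropolis update per free process parameter per sweep, then one
per distortion innovation. Innovations are parameterised non-centredly
(`ε = τ·ξ` with `ξ ~ N(0,1)`), which removes the funnel between `τ` and the
distortions when the data only weakly identify `τ`. Proposal scales adapt
during warmup toward 44% acceptance (Robbins–Monro, gain `2/√sweep`) and
are frozen afterwards, so the post-warmup chain is a valid fixed-kernel
sampler. Defaults are 4 chains × 5000 post-warmup iterations after 2000
warmup; tests and the validation harness run 2 chains × 300–1000
iterations, which experimentation during development showed is enough for
stable medians and 95% intervals at this model size (around 80 latent
quantities for a 35-year grid). Convergence is monitored by split-chain
R-hat and autocorrelation-based effective sample size for mCPR at the
first, middle and last grid year; failures warn rather than abort (with the
warning count recorded), so that multi-country validation sweeps always
complete and report.

All randomness flows from the seed in `fit_config()`; identical data,
configuration and seed give bit-identical posteriors. The sampler consumes
R's RNG stream, so chains run sequentially and reproducibly.

## Synthetic-data generator

`generate_cohort()` emulates the structure of the national survey and EMU
databases this model family is built for — it is the package's stand-in
for data that cannot be redistributed:

* per-country process parameters drawn from hyper-distributions that
  default to the fitting priors (so generated cohorts are correctly
  specified for calibration studies); initial states default to
  `η_0 ~ N(−2.5, 1)`, `ζ_0 ~ N(0, 1)`, putting early total prevalence
  around 5–10% with a rising trend;
* surveys every 3–5 years with independent proportion-scale Gaussian
  sampling noise (sd 0.01) on modern and traditional use, clipped to the
  interior of the simplex, labelled alternately DHS/MICS;
* per country 1–3 EMU source types (probabilities 0.50/0.36/0.14, the
  mix observed in the 2018 EMU database), each series built as
  `z_t = ρ_t + b + W_t` with a persistent level offset `b ~ N(0, 0.1²)`
  drawn once per series and a random walk `W_t` whose increments are
  N(0, σ_s²) — so that `z_t − z_{t−1} = (ρ_t − ρ_{t−1}) + N(0, σ_s²)`
  holds *exactly* by construction, the generative mirror of the EMU data
  model. Series default to 8 years ending two years after the country's
  last survey. Values are clipped to [0, 1] with a count of clip events.

Parameter draws are rejected (and redrawn) when the realized trajectory's
mCPR is still below 2% at the end of the horizon: such draws emulate a
country without a functioning family planning program, which the log-ratio
survey model — like the survey instruments themselves — does not cover,
and which the application-domain databases do not contain. This bounds the
generator to the method's operating range; it also means generated cohorts
are a (slightly) truncated version of the prior, which is visible as mild
conservatism in calibration checks.

Two numerical details exist so that the package's invariances hold exactly
rather than to rounding error: EMU values are stored on a dyadic grid
(multiples of 2⁻²⁶), and level shifts used in tests are dyadic constants.
Floating-point addition is exact on that grid, so `diff(z + c)` is
bit-identical to `diff(z)` and a fitted posterior is bit-invariant to the
level bias — the first-difference model's defining property, verifiable
with `identical()` rather than a tolerance.

What the generator does **not** emulate: raw service-statistic counts
upstream of EMU (commodity-to-user conversion, private-sector adjustment),
reporting-rate artifacts within a year, drifting (rather than constant)
level bias, survey microdata or design effects, and subnational structure.
Passing calibration tests on generated cohorts therefore demonstrates
internal consistency of model and generator under these assumptions, not
performance on any real country's data.

## Validation harness

`run_validation()` mirrors standard out-of-sample practice for this model
family: per country the most recent survey is held out (ties broken by
stable input order and flagged; single-survey countries dropped with a
notice), both model variants are fitted to the remainder, and the held-out
modern prevalence is scored against the posterior at the test year by

* coverage of the central 95% interval,
* mean error and RMSE of the posterior median (proportion scale),
* the mean interval score at α = 0.05: width plus `2/α` times the breach
  distance when the observation falls outside — a proper scoring rule that
  rewards narrow intervals and penalises misses. The score is averaged per
  observation on the proportion scale.

The EMU arm keeps a single source type per country — preferring the type
with the smallest `σ_s` (facilities, visits, clients, users), matching how
a practitioner would pick the most reliable series — and drops countries
with no EMU observation after the latest training survey, since EMU data
entirely inside the training period cannot inform the prediction. Both
arms are evaluated on the intersection of countries completing both, so
the comparison is paired. Per-country fit failures are skipped and
tallied, erroring only if no country completes.

`compare_runs()` reports, for a target year, the difference in posterior
medians, its absolute value, and the difference in 95% interval widths
between two runs, in percentage points — the quantities used to describe
the impact of adding EMU data to a country's fit.

## Problem sizes and runtime

The shipped tests and the acceptance script use: 20-country cohorts with 2
chains × 800 iterations (500 warmup) per fit for hold-out validation
(~30 s); 200 change pairs per source type × 50 replicates for the variance
estimator; a 3-year toy model with all process parameters fixed for the
grid-oracle comparison (101³ grid nodes); and 2 chains × 1000 iterations
for the directional-impact scenarios. These sizes were chosen as the
smallest at which the Monte-Carlo noise of each check is comfortably below
the effect it measures.

## Known limitations

* Single-country likelihoods only: no hierarchical pooling across
  countries, so prior settings matter more than in a global model, and
  countries with one survey cannot be fitted meaningfully.
* The log-ratio survey model degenerates near zero prevalence; the package
  targets countries with established programs (mCPR of at least a few
  percent).
* EMU series affect estimates only through adjacent-year (or optionally
  gap-scaled) differences; a series with no two usable observations is
  silently uninformative (with a warning).
* `σ_s` is treated as known in the likelihood; its sampling uncertainty
  from `estimate_sigma()` is reported (`n_pairs`) but not propagated.
* The random-walk sampler mixes slowly for early, prior-dominated years of
  long grids (visible as low ESS at the first grid year); estimates and
  projections near and beyond the data are unaffected, but users needing
  tight early-period inference should raise iterations.
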