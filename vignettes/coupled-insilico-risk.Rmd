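---
title: "Methods: SSD-based risk assessment with coupled in-silico toxicity extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSD-based risk assessment with coupled in-silico toxicity extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdrisk)
```

## Scope and model

`ssdrisk` derives predicted no-effect concentrations (PNECs) and per-site
risk quotients (RQs) for chemicals whose chronic toxicity data are too
sparse for a direct species sensitivity distribution (SSD). The pipeline
is screen → extrapolate → fit → hazard concentration → PNEC → RQ; each
stage is an exported function and `run_pipeline()` chains them from one
declarative configuration.

The central statistical object is the SSD: per-species chronic
sensitivities (here NOEC concentrations in µg/L) are treated as i.i.d.
draws from a continuous distribution over species. We parameterise every
supported family as a location–scale model on the natural-log
concentration scale, `ln X = μ + σZ`, with `Z` standard normal
(log-normal family), standard logistic (log-logistic) or standard Gumbel
(log-Gumbel, i.e. inverse Weibull). The log-normal density in x is

$$f(x) = \frac{1}{x\sigma\sqrt{2\pi}}
  \exp\!\left(-\tfrac12\left(\frac{\ln x - \mu}{\sigma}\right)^2\right),
  \qquad x > 0,$$

so μ is the mean and σ the standard deviation of the ln-transformed
data. The hazard concentration for a fraction *p* of species is the *p*
quantile, `HCp = exp(μ + σ·q_Z(p))`; `p = 0.05` gives the HC5 used for
PNEC derivation, `PNEC = HC5 / AF` with assessment factor `AF ∈ [1, 5]`
(default 5, the conservative end). A site's risk quotient is
`RQ = MEC / PNEC`, computed once from the site's mean concentration
(average case) and once from its maximum (most severe case), and
classified high (≥ 1), moderate ([0.1, 1)), low ([0.01, 0.1)) or
negligible (< 0.01).

Assumptions worth stating explicitly: species sensitivities are
exchangeable (no phylogenetic weighting); one value per species (multiple
records are collapsed to their geometric mean before fitting);
concentrations are exact, not censored; and sites are assessed
independently (no spatiotemporal structure).

## Estimation and numerical choices

**Maximum likelihood.** For the log-normal family the MLE is closed form:
μ̂ is the mean of the ln-values and σ̂ the ln-scale standard deviation
with divisor *n*. The divisor matters at SSD sample sizes: with the
packaged twelve-species dataset, divisor *n* puts the HC5 at 39.77 µg/L
while the `n − 1` variant would give ≈ 35 µg/L. We use the true MLE
(divisor *n*) throughout; tests verify equality with a brute-force
likelihood search. For the log-logistic and log-Gumbel families the
likelihood is maximised numerically with BFGS on `(μ, ln σ)` — the `ln σ`
transform keeps the scale positive without constraints — starting from
moment-matched values (`σ√3/π` and `σ√6/π` respectively, with the Euler
–Mascheroni shift for the Gumbel location) and a relative convergence
tolerance of 1e−10; non-convergence is an error, never a silent result.

**Goodness of fit.** Family choice is by AIC (`2k − 2ℓ` with `k = 2`);
ties below 1e−9 break toward the log-normal family. The
Kolmogorov–Smirnov statistic is the exact sup-distance over the sorted
sample, `max_i max(|i/n − F(x₍ᵢ₎)|, |F(x₍ᵢ₎) − (i−1)/n|)`, and the
Anderson–Darling statistic is
`−n − (1/n)Σ(2i−1)[ln F(x₍ᵢ₎) + ln(1 − F(x₍ₙ₊₁₋ᵢ₎))]`. Because the
parameters are estimated from the same sample, the textbook null
distributions for these statistics do not apply; we therefore report the
statistics and AIC but deliberately no p-values.

**Bootstrap.** Confidence intervals for HCp come from a parametric
bootstrap: `n_boot` resamples of size *n* are drawn from the fitted
distribution (inverse-CDF sampling, so one uniform stream serves every
family), each resample is refitted, and the 2.5th/97.5th percentiles of
the replicate HCp values form the 95 % interval. The seed is a required
argument — intervals are exactly reproducible — and replicate fitting
failures above 5 % abort with diagnostics. Default `n_boot = 1000`
(2000 in the reference recomputation); below 1000 a warning flags noisy
limits. A known property of this estimator at SSD sample sizes deserves
emphasis: at `n = 12` the nominal 95 % percentile interval undercovers —
our seeded simulations measure true coverage of roughly 0.8–0.85 against
the analytic HC5 — so the intervals should be read as approximate. The
test suite bounds the measured recovery rate rather than asserting the
nominal level.

**Units and logs.** Every concentration inside the package is µg/L;
the occurrence reader converts its ng/L inputs by ×10⁻³ at the boundary,
and the writer converts back, so unit handling lives only in I/O code.
SSD parameters are on the natural-log scale; base-10 logarithms appear
only in the ICE relation and displays.

## Screening

Records are retained iff endpoint = NOEC, effect class = chronic lethal,
duration ≥ 4 d (algae) / ≥ 21 d (other groups), and the curator-set
standard-method flag is true; rejections carry the first failing rule
(checked in that order). All thresholds are overridable through
`screening_rules()`. The packaged twelve-species BPA table contains an
insect tested 4 d and an amphibian tested 14 d — records that the stated
duration policy rejects even though the curated dataset keeps them. We
ship both policies: the defaults apply the rules literally (10 species
retained), and `screening_rules_table4_compat()` waives the duration rule
for insects and amphibians to reproduce the published twelve-species
dataset. The inconsistency is surfaced, not resolved.

## ICE extrapolation

An ICE model predicts one species' toxicity from a surrogate species'
toxicity for the same chemical via `log10 T_pred = a·log10 T_sur + b`.
The registry (slope, intercept, R², MSE, cross-validation success,
p-value per pair) is filtered by the conventional quality guidelines
(R² > 0.6, MSE < 0.95, slope > 0.6, cross-validation > 60 %, p < 0.01) —
the packaged six-model registry passes in full, including the
*Pseudosida ramosa* model whose printed p-value 0.006 sits closest to the
cut. Censored p-values printed as "<0.001" are parsed as their upper
bound. Dataset assembly couples a surrogate set (externally obtained,
e.g. QSAR predictions for one fish, one crustacean, one alga) with every
applicable model: the output has one record per surrogate plus one per
model, e.g. 3 + 6 = 9 species. Two deliberate refusals: chained
extrapolation (feeding an ICE prediction into another model as its
surrogate) is not performed, because the regressions are pairwise
calibrations and chaining compounds unquantified error; and no
uncertainty is propagated through ICE point predictions — MSE is carried
as metadata only.

Intercept units: ICE registries are calibrated on a specific
concentration unit, and with near-unit slopes the unit convention shifts
only the intercept's meaning. This package applies intercepts on
log10-µg/L, matching a pipeline whose SSD outputs are reported in µg/L;
recalibrating to mg/L would be a registry-level change, not a code
change.

## Synthetic data

The generators produce inputs with exactly the structure the analysis
assumes, so every stage is testable without downloads, and all are pure
functions of (parameters, seed):

* `gen_toxicity_dataset()` draws ln-sensitivities i.i.d. from N(μ, σ²) —
  the defaults in tests mirror the packaged BPA dataset's fitted values
  (μ = 6.357, σ = 1.626, n = 12);
* `gen_surrogate_and_ice_truth()` applies the registry exactly and
  perturbs log10 predictions with N(0, residual_sd²); residual_sd = 0 is
  the noise-free oracle used to pin the predictor;
* `gen_concentration_table()` builds each site's min/mean/max as order
  statistics of k = 8 log-normal observations around a log-normal
  site-level median (so min ≤ mean ≤ max holds by construction), zeroing
  observations below the detection limit and emitting all-censored sites
  as non-detects.

What the generators do **not** emulate: correlated sensitivities across
related species, censored or interval-valued endpoints, inter-laboratory
variance in toxicity tests, and spatial or temporal correlation between
sites. Passing tests therefore demonstrate the estimators' behaviour
under the model's own assumptions, not robustness to their violation in
field data.

Test problem sizes were chosen to characterise small-sample behaviour at
realistic SSD scale: parameter recovery uses 500 replicates at n = 12,
coverage checks 200 datasets with 400-replicate bootstraps, and family
selection consistency one draw of n = 1000.

## Design decisions

* **Non-detects are zeros with a flag.** Occurrence tables report ND
  rows; we represent them as concentration 0 with `detected = FALSE`,
  which matches how the packaged tables' published summaries treat them
  (mean-RQ lower bounds of literally 0). The flag keeps stricter policies
  (e.g. DL/2 substitution) implementable without schema change. The "/"
  token (no data) is distinct: those records carry NA and are excluded
  from summaries and risk tables.
* **RQ = 1 is high risk.** Published band definitions conventionally
  overlap at 1 (moderate "≤ 1", high "≥ 1"); we resolve the boundary
  conservatively.
* **A fourth tier, negligible.** RQ < 0.01 falls below the conventional
  three-band scheme's lowest band; we add "negligible" rather than stretch
  "low", preserving the published bands verbatim.
* **PNEC source is a run parameter.** For BPA both an
  experimental-dataset PNEC (7.96 µg/L from HC5 = 39.8) and an in-silico
  one (8.04 µg/L from HC5 = 40.2) are defensible; published worked RQ
  values are consistent with 7.96, so that is the default in examples,
  and both tags travel with `pnec_result` rows.
* **No model averaging.** The AIC table is reported and a single family
  selected; model-averaged SSDs are out of scope.

## Limitations

The ICE stage accepts surrogate values as given — the upstream QSAR
models are a black box whose outputs are inputs here, so the in-silico
HC5 can only be recomputed when those surrogate values are supplied.
Percentile-bootstrap undercoverage at small n is documented above.
Likelihoods are uncensored; "greater-than" NOECs cannot be represented.
Risk characterisation is deterministic (point MEC over point PNEC), not
probabilistic.
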