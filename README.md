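# ssdrisk

Ecological risk assessment of data-poor chemicals from species sensitivity
distributions (SSDs), with interspecies toxicity extrapolation to fill data
gaps.

## The problem

Deriving a predicted no-effect concentration (PNEC) for a chemical requires
chronic toxicity values for many species — SSD guidance asks for at least
5–10 — but for replacement chemicals such as the bisphenol A substitutes
BPS and BPF, measured chronic data barely exist. A practical workaround is
to couple two in-silico sources: structure-based (QSAR) predictions supply
toxicity values for one surrogate species per trophic level, and
interspecies correlation estimation (ICE) regressions extrapolate each
surrogate value to further species. The pooled multi-species dataset then
supports an SSD like any measured dataset.

`ssdrisk` implements that workflow end to end for risk assessors and
ecotoxicologists:

* **screening** of chronic records (NOEC endpoints, chronic lethal effects,
  minimum exposure durations of 4 d for algae / 21 d otherwise,
  standard-method provenance), with per-record rejection reasons;
* **ICE extrapolation** `log10 T_pred = a · log10 T_sur + b` from a
  quality-filtered model registry (R² > 0.6, MSE < 0.95, slope > 0.6,
  cross-validation success > 60 %, p < 0.01);
* **SSD fitting** by maximum likelihood for the log-normal, log-logistic
  and log-Gumbel families on the natural-log concentration scale, with
  Kolmogorov–Smirnov and Anderson–Darling statistics and AIC-based family
  selection. For the log-normal family, `ln X ~ N(μ, σ²)` with the MLE
  `σ̂` using divisor *n*;
* **hazard concentrations** `HC5 = exp(μ̂ + σ̂ z₀.₀₅)` with seeded
  parametric-bootstrap 95 % confidence intervals, and
  `PNEC = HC5 / AF` with an assessment factor AF ∈ [1, 5];
* **risk quotients** `RQ = MEC / PNEC` per monitoring site, classified as
  high (RQ ≥ 1), moderate ([0.1, 1)), low ([0.01, 0.1)) or negligible
  (< 0.01);
* **seeded generators** for synthetic toxicity datasets, ICE truth sets
  and site concentration tables with non-detects.

Curated fixtures ship with the package: twelve chronic BPA NOECs, six
Web-ICE-style extrapolation models, and min/mean/max occurrence data for
BPA/BPS/BPF across 32 Chinese surface waters (ng/L, converted to the
package-wide µg/L at the reader).

## Worked example

```r
library(ssdrisk)

cfg <- pipeline_config(
  chemical            = "BPA",
  mode                = "experimental",
  toxicity_table      = ssdrisk_example("bpa_toxicity"),
  concentration_table = ssdrisk_example("concentrations"),
  rules               = "table4_compat",  # keep all 12 packaged species
  n_boot              = 2000,
  seed                = 42)
report <- run_pipeline(cfg, quiet = TRUE)
report
#> Risk assessment report: BPA (experimental dataset)
#>   species: 12 (from 12 input records, 0 rejected)
#>   SSD: log_normal, mu = 6.3571, sigma = 1.6257
#>   HC5 = 39.77 ug/L (95% CI 10.43-188.9; 2000 bootstrap reps, seed 42)
#>   PNEC = 7.954 ug/L (AF = 5)
#>   RQ (mean-based): 0.00105-0.116 over 32 sites; max-based peak 0.94
#>   config md5: 726d9a21dcff97ca69ec80b05d74df6a
```

Reading the numbers: the twelve-species log-normal SSD puts the
concentration hazardous to 5 % of species at 39.77 µg/L; dividing by the
assessment factor 5 gives a PNEC of 7.95 µg/L. Against the 32 monitoring
sites, average-case risk quotients span 0.00105–0.116 (all below the
moderate-risk line except one site) and the worst-case (maximum
concentration) quotient reaches 0.94, just under the high-risk threshold.

The per-family goodness-of-fit table shows why the log-normal family is
selected (lowest AIC):

```r
report$gof_table
#> # A tibble: 3 × 8
#>   family          mu sigma     n log_likelihood   aic ks_stat ad_stat
#>   <chr>        <dbl> <dbl> <int>          <dbl> <dbl>   <dbl>   <dbl>
#> 1 log_normal    6.36 1.63     12          -99.1  202.   0.207   0.450
#> 2 log_logistic  6.48 0.973    12          -99.6  203.   0.187   0.435
#> 3 log_gumbel    5.51 1.65     12         -100.   205.   0.204   0.577
```

The in-silico route assembles its dataset from three surrogate values and
the packaged ICE registry instead:

```r
sur <- c("Oryzias latipes" = 598, "Daphnia magna" = 5000,
         "Pseudokirchneriella subcapitata" = 3995)
cfg2 <- pipeline_config(chemical = "BPA", mode = "in_silico",
                        surrogate_values = sur,
                        ice_table = ssdrisk_example("ice_models"),
                        n_boot = 2000, seed = 42)
run_pipeline(cfg2, quiet = TRUE)$manifest$counts$species
#> [1] 9
```

A thin command-line front end over the same functions lives at
`inst/cli/ssdrisk.R` (subcommands `run`, `screen`, `extrapolate`,
`fit-ssd`, `derive-pnec`, `assess-risk`, `simulate`).

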