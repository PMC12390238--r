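# Seeded generators producing inputs with the statistical structure the
# analysis assumes: log-normal interspecies sensitivity, log10-linear
# surrogate->predicted toxicity with Gaussian residuals, and right-skewed
# site concentrations with non-detects. All generators are pure functions
# of (parameters, seed).

#' Generate a synthetic chronic toxicity dataset
#'
#' Draws species sensitivities i.i.d. from a log-normal distribution on the
#' natural-log ug/L scale — the interspecies variation model behind the
#' SSD. Species names are synthetic and unique; endpoint, effect class,
#' duration and provenance are populated so the records pass default
#' screening unchanged.
#'
#' @param mu Location on the ln-ug/L scale.
#' @param sigma Scale on the ln scale, positive.
#' @param n Number of species, at least 2.
#' @param seed Integer seed (required; generation is deterministic).
#' @param groups Optional named weights over taxonomic groups used to
#'   assign group labels; defaults to uniform over the six conventional
#'   groups.
#' @return A `toxicity_records` tibble.
#' @export
#' @examples
#' gen_toxicity_dataset(mu = 6.36, sigma = 1.63, n = 12, seed = 1)
gen_toxicity_dataset <- function(mu, sigma, n, seed, groups = NULL) {
  stopifnot_scalar_number(mu, "mu")
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("`n` must be a single integer >= 2.", class = "ssdrisk_error_domain")
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep(1, length(toxicity_groups)), toxicity_groups)
  }
  withr::with_seed(seed, {
    conc <- exp(stats::rnorm(n, mu, sigma))
    grp <- sample(names(groups), n, replace = TRUE,
                  prob = groups / sum(groups))
    toxicity_records(
      species = sprintf("Simulatus species%03d", seq_len(n)),
      group = grp,
      concentration = conc,
      duration = ifelse(grp == "algae", 4, 28),
      source = "synthetic",
      provenance_ok = TRUE
    )
  })
}

#' Generate surrogate values and noisy ICE predictions with known truth
#'
#' Takes true surrogate toxicity values, applies each ICE model exactly,
#' and optionally perturbs the predictions on the log10 scale with
#' Gaussian noise of standard deviation `residual_sd` — the residual
#' structure the models' MSE quantifies. With `residual_sd = 0` the noisy
#' predictions coincide with [ice_predict()] output, which makes this the
#' noise-free oracle for extrapolation tests.
#'
#' @param true_values Named numeric vector species -> concentration ug/L.
#' @param models An `ice_models` tibble.
#' @param residual_sd Residual standard deviation in log10 units, >= 0.
#' @param seed Integer seed.
#' @param chemical Chemical label for the surrogate set.
#' @return List with `surrogates` (a [surrogate_set()]) and `predictions`
#'   (tibble: `predicted_species`, `surrogate_species`, `noise_free`,
#'   `noisy`, both ug/L).
#' @export
gen_surrogate_and_ice_truth <- function(true_values, models, residual_sd = 0,
                                        seed = 1, chemical = "SYN") {
  if (residual_sd < 0) {
    abort("`residual_sd` must be non-negative.", class = "ssdrisk_error_domain")
  }
  surrogates <- surrogate_set(chemical, true_values)
  if (nrow(models) == 0L) {
    return(list(surrogates = surrogates,
                predictions = tibble(predicted_species = character(),
                                     surrogate_species = character(),
                                     noise_free = numeric(),
                                     noisy = numeric())))
  }
  applicable <- models$surrogate_species %in% names(true_values)
  models <- models[applicable, , drop = FALSE]
  noise_free <- vapply(seq_len(nrow(models)), function(i) {
    ice_predict(models[i, ], true_values[[models$surrogate_species[i]]])
  }, numeric(1))
  noisy <- withr::with_seed(seed, {
    10^(log10(noise_free) + stats::rnorm(length(noise_free), 0, residual_sd))
  })
  list(
    surrogates = surrogates,
    predictions = tibble(
      predicted_species = models$predicted_species,
      surrogate_species = models$surrogate_species,
      noise_free = noise_free,
      noisy = noisy
    )
  )
}

#' Generate a synthetic site concentration table
#'
#' Emulates monitoring summaries: per site, `k` individual observations are
#' drawn log-normally around a site-level median (itself log-normally
#' distributed across sites), and the reported min/mean/max are the order
#' statistics of those observations — which guarantees min <= mean <= max
#' by construction. Observations below the detection limit are zeroed; a
#' site where all observations fall below the limit becomes a non-detect
#' record.
#'
#' @param n_sites Number of sites, at least 1.
#' @param log10_mean Across-site mean of the site-level median, log10 ng/L.
#' @param log10_sd Across-site standard deviation, log10 units.
#' @param detection_limit Detection limit in ng/L (0 disables censoring).
#' @param seed Integer seed.
#' @param chemical Chemical label.
#' @param k Observations per site behind the reported summaries.
#' @param within_sd Within-site spread, log10 units.
#' @return A `concentration_records` tibble (concentrations in ug/L).
#' @export
#' @examples
#' gen_concentration_table(5, log10_mean = 2, log10_sd = 0.5,
#'                         detection_limit = 1, seed = 7)
gen_concentration_table <- function(n_sites, log10_mean, log10_sd,
                                    detection_limit = 0, seed,
                                    chemical = "SYN", k = 8,
                                    within_sd = 0.3) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1) {
    abort("`n_sites` must be a single integer >= 1.",
          class = "ssdrisk_error_domain")
  }
  withr::with_seed(seed, {
    site_med <- stats::rnorm(n_sites, log10_mean, log10_sd)
    rows <- purrr::map(seq_len(n_sites), function(i) {
      obs <- 10^stats::rnorm(k, site_med[i], within_sd) # ng/L
      obs[obs < detection_limit] <- 0
      detected <- any(obs > 0)
      tibble(
        site_id = i,
        location = sprintf("Synthetic site %02d", i),
        sampling_year = 2020L,
        chemical = chemical,
        conc_min = ng_to_ug(if (detected) min(obs) else 0),
        conc_max = ng_to_ug(if (detected) max(obs) else 0),
        conc_mean = ng_to_ug(if (detected) mean(obs) else 0),
        detected = detected,
        missing_data = FALSE,
        source = "synthetic"
      )
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- union("concentration_records", class(out))
    out
  })
}
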