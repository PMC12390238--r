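ssd_rquantile <- function(fit, n) {
  # inverse-CDF sampling keeps the generator uniform across families
  exp(fit$mu + fit$sigma * family_funs(fit$family)$qz(stats::runif(n)))
}

#' Parametric-bootstrap confidence interval for a hazard concentration
#'
#' Fits the chosen family to `values`, then draws `n_boot` parametric
#' resamples of the same size from the fitted distribution, refits each
#' resample, and takes the HC-p of every replicate. The 95% confidence
#' interval is the 2.5th/97.5th percentile of the replicate HC values.
#' The seed is mandatory so that intervals are exactly reproducible.
#'
#' @param values Species sensitivity concentrations in ug/L.
#' @param family SSD family (see [fit_ssd()]).
#' @param p Proportion of species, default 0.05 (HC5).
#' @param n_boot Number of bootstrap replicates, at least 100; a warning is
#'   issued below 1000.
#' @param seed Integer seed (required).
#' @param level Confidence level, default 0.95.
#' @return An `hc_estimate`: `p`, `point`, `ci_lower`, `ci_upper`,
#'   `n_boot`, `seed`, `n_failed`, `fit`.
#' @export
#' @examples
#' tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
#' bootstrap_hc(tox$concentration, n_boot = 200, seed = 42)
bootstrap_hc <- function(values, family = "log_normal", p = 0.05,
                         n_boot = 1000, seed, level = 0.95) {
  if (missing(seed)) {
    abort("`seed` is required: bootstrap intervals must be reproducible.",
          class = "ssdrisk_error_config")
  }
  if (n_boot < 100) {
    abort("`n_boot` must be at least 100.", class = "ssdrisk_error_domain")
  }
  if (n_boot < 1000) {
    warn("n_boot < 1000: confidence limits will be noisy.")
  }
  fit <- fit_ssd(values, family)
  point <- hc_quantile(fit, p)
  n <- fit$n

  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      smp <- ssd_rquantile(fit, n)
      refit <- tryCatch(suppressWarnings(fit_ssd(smp, family)),
                        error = function(e) NULL)
      if (is.null(refit)) NA_real_ else hc_quantile(refit, p)
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed / n_boot > 0.05) {
    abort(sprintf(
      "Bootstrap replicate fitting failed in %d/%d draws (family %s, n %d).",
      n_failed, n_boot, family, n), class = "ssdrisk_error_fit")
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(
    list(p = p, point = point, ci_lower = ci[1], ci_upper = ci[2],
         level = level, n_boot = n_boot, seed = seed, n_failed = n_failed,
         fit = fit),
    class = "hc_estimate"
  )
}

#' @export
print.hc_estimate <- function(x, ...) {
  cat(sprintf("HC%g = %.4g ug/L (%g%% CI %.4g-%.4g)\n",
              100 * x$p, x$point, 100 * x$level, x$ci_lower, x$ci_upper))
  cat(sprintf("  %s fit, n = %d species; %d bootstrap replicates (seed %d)\n",
              x$fit$family, x$fit$n, x$n_boot, x$seed))
  invisible(x)
}
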