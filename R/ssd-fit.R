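ssd_families <- c("log_normal", "log_logistic", "log_gumbel")

# Family internals. Every family is a location-scale model on the natural-log
# concentration scale: ln X = mu + sigma * Z with Z standard normal, standard
# logistic, or standard Gumbel (max). Quantile/cdf/log-density of Z:
family_funs <- function(family) {
  switch(family,
    log_normal = list(
      qz = stats::qnorm,
      pz = stats::pnorm,
      ldz = function(z) stats::dnorm(z, log = TRUE)
    ),
    log_logistic = list(
      qz = function(p) log(p / (1 - p)),
      pz = stats::plogis,
      ldz = function(z) -z - 2 * log1p(exp(-z))
    ),
    log_gumbel = list(
      qz = function(p) -log(-log(p)),
      pz = function(z) exp(-exp(-z)),
      ldz = function(z) -z - exp(-z)
    ),
    abort(sprintf("Unknown SSD family '%s'.", family),
          class = "ssdrisk_error_config")
  )
}

new_ssd_fit <- function(family, mu, sigma, n, log_likelihood,
                        values = NULL, ks_stat = NA_real_,
                        ad_stat = NA_real_) {
  structure(
    list(family = family, mu = mu, sigma = sigma, n = n,
         log_likelihood = log_likelihood,
         aic = 2 * 2 - 2 * log_likelihood,
         ks_stat = ks_stat, ad_stat = ad_stat, values = values),
    class = "ssd_fit"
  )
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("SSD fit: %s (n = %d species)\n", x$family, x$n))
  cat(sprintf("  mu = %.4f, sigma = %.4f (ln ug/L)\n", x$mu, x$sigma))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, KS = %.4f, AD = %.4f\n",
              x$log_likelihood, x$aic, x$ks_stat, x$ad_stat))
  cat(sprintf("  HC5 = %.4g ug/L\n", hc_quantile(x, 0.05)))
  invisible(x)
}

check_ssd_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    abort("At least 2 positive toxicity values are required.",
          class = "ssdrisk_error_domain")
  }
  if (any(!is.finite(values) | values <= 0)) {
    abort("All toxicity values must be finite and strictly positive (ug/L).",
          class = "ssdrisk_error_domain")
  }
  if (length(values) < 5L) {
    warn("Fewer than 5 species: SSD estimates will be very uncertain (recommended minimum sample sizes are 5-10).")
  }
  if (stats::sd(log(values)) == 0) {
    abort("All values identical: the sensitivity distribution is degenerate (sigma = 0).",
          class = "ssdrisk_error_degenerate")
  }
  values
}

ln_loglik <- function(family, lx, mu, sigma) {
  f <- family_funs(family)
  # density of X: f_Z((ln x - mu)/sigma) / (sigma x)
  sum(f$ldz((lx - mu) / sigma)) - length(lx) * log(sigma) - sum(lx)
}

#' Fit a species sensitivity distribution by maximum likelihood
#'
#' Fits a two-parameter location-scale distribution to ln-transformed
#' species sensitivity values. For the log-normal family the maximum
#' likelihood estimates are closed form: `mu` is the mean of the
#' ln-values and `sigma` the ln-scale standard deviation with divisor `n`
#' (the MLE, not the `n - 1` sample version). The log-logistic and
#' log-Gumbel families are fitted numerically on `(mu, log sigma)` from
#' moment-matched starting values. Kolmogorov-Smirnov and Anderson-Darling
#' statistics and AIC are computed on the fit.
#'
#' @param values Species sensitivity concentrations in ug/L (one per
#'   species), at least 2, strictly positive. A warning is issued below 5.
#' @param family `"log_normal"` (default), `"log_logistic"` or
#'   `"log_gumbel"`.
#' @return An `ssd_fit` object: `family`, `mu`, `sigma` (natural-log ug/L
#'   scale), `n`, `log_likelihood`, `aic`, `ks_stat`, `ad_stat`.
#' @export
#' @examples
#' tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
#' fit <- fit_ssd(tox$concentration)
#' fit
fit_ssd <- function(values, family = c("log_normal", "log_logistic",
                                       "log_gumbel")) {
  family <- match.arg(family)
  values <- check_ssd_values(values)
  lx <- log(values)
  n <- length(lx)

  if (family == "log_normal") {
    mu <- mean(lx)
    sigma <- sqrt(sum((lx - mu)^2) / n)
    ll <- ln_loglik(family, lx, mu, sigma)
  } else {
    m0 <- mean(lx)
    s0 <- stats::sd(lx) * if (family == "log_logistic") sqrt(3) / pi else sqrt(6) / pi
    if (family == "log_gumbel") m0 <- m0 - 0.5772156649 * s0
    nll <- function(p) -ln_loglik(family, lx, p[1], exp(p[2]))
    opt <- stats::optim(c(m0, log(s0)), nll, method = "BFGS",
                        control = list(reltol = 1e-10, maxit = 500))
    if (opt$convergence != 0) {
      abort(sprintf("MLE for family '%s' did not converge (optim code %d).",
                    family, opt$convergence),
            class = "ssdrisk_error_fit")
    }
    mu <- opt$par[1]
    sigma <- exp(opt$par[2])
    ll <- -opt$value
  }
  fit <- new_ssd_fit(family, mu, sigma, n, ll, values = values)
  gof <- gof_statistics(fit, values)
  fit$ks_stat <- gof$ks_stat
  fit$ad_stat <- gof$ad_stat
  fit
}

#' Fitted cumulative sensitivity distribution
#'
#' @param fit An `ssd_fit`.
#' @param x Concentrations in ug/L.
#' @return Fraction of species affected at each concentration.
#' @export
ssd_cdf <- function(fit, x) {
  family_funs(fit$family)$pz((log(x) - fit$mu) / fit$sigma)
}

#' Goodness-of-fit statistics for a fitted SSD
#'
#' Computes the Kolmogorov-Smirnov statistic
#' `sup_i max(|i/n - F(x_(i))|, |F(x_(i)) - (i-1)/n|)` and the
#' Anderson-Darling statistic
#' `-n - (1/n) * sum (2i-1) * (ln F(x_(i)) + ln(1 - F(x_(n+1-i))))`
#' against the fitted CDF, plus the AIC. Statistics only: because the
#' parameters were estimated from the same data, the textbook null
#' distributions (and hence p-values) do not apply and are deliberately
#' not reported.
#'
#' @param fit An `ssd_fit` produced from `values`.
#' @param values The concentrations the fit was produced from (ug/L).
#' @return List with `ks_stat`, `ad_stat`, `aic`.
#' @export
gof_statistics <- function(fit, values = fit$values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  Fx <- ssd_cdf(fit, x)
  i <- seq_len(n)
  ks <- max(pmax(abs(i / n - Fx), abs(Fx - (i - 1) / n)))
  ad <- -n - mean((2 * i - 1) * (log(Fx) + log(1 - rev(Fx))))
  list(ks_stat = ks, ad_stat = ad, aic = fit$aic)
}

#' Fit several families and select the best by AIC
#'
#' Fits each candidate family to the same data and returns the fit with
#' the smallest AIC (lower is better) together with the per-family
#' goodness-of-fit table. Numerical AIC ties (difference below 1e-9) are
#' broken in favour of the log-normal family.
#'
#' @param values Species sensitivity concentrations in ug/L.
#' @param families Candidate families.
#' @return List with `best` (an `ssd_fit`) and `table` (a tibble with one
#'   row per family that fitted successfully).
#' @export
#' @examples
#' tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
#' sel <- select_family(tox$concentration)
#' sel$best$family
#' sel$table
select_family <- function(values, families = ssd_families) {
  fits <- list()
  failures <- character()
  for (fam in families) {
    f <- tryCatch(fit_ssd(values, fam), error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, sprintf("%s: %s", fam, conditionMessage(f)))
    } else {
      fits[[fam]] <- f
    }
  }
  if (length(fits) == 0L) {
    abort(paste0("All SSD fits failed. ", paste(failures, collapse = "; ")),
          class = "ssdrisk_error_fit")
  }
  tab <- purrr::map_dfr(fits, function(f) {
    tibble(family = f$family, mu = f$mu, sigma = f$sigma, n = f$n,
           log_likelihood = f$log_likelihood, aic = f$aic,
           ks_stat = f$ks_stat, ad_stat = f$ad_stat)
  })
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best_aic <- min(aics)
  tied <- names(fits)[aics - best_aic < 1e-9]
  best <- if ("log_normal" %in% tied) "log_normal" else tied[[1]]
  list(best = fits[[best]], table = tab)
}

#' Hazard-concentration quantile of a fitted SSD
#'
#' The concentration hazardous to a proportion `p` of species: the `p`
#' quantile of the fitted distribution. For `p = 0.05` this is the HC5.
#' Closed forms: log-normal `exp(mu + sigma * z_p)`; log-logistic
#' `exp(mu + sigma * ln(p/(1-p)))`; log-Gumbel `exp(mu - sigma *
#' ln(-ln p))`.
#'
#' @param fit An `ssd_fit`.
#' @param p Proportion(s) of species in (0, 1).
#' @return Concentration(s) in ug/L.
#' @export
#' @examples
#' tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
#' hc_quantile(fit_ssd(tox$concentration), 0.05) # ~39.8 ug/L
hc_quantile <- function(fit, p = 0.05) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    abort("`p` must lie strictly between 0 and 1.",
          class = "ssdrisk_error_domain")
  }
  exp(fit$mu + fit$sigma * family_funs(fit$family)$qz(p))
}

#' Plot a fitted SSD against the empirical species ranks
#'
#' Empirical points at Hazen plotting positions `(i - 0.5) / n` on a
#' log-scaled concentration axis, with the fitted cumulative curve.
#'
#' @param fit An `ssd_fit` carrying its data.
#' @param show_hc5 Draw the HC5 reference lines.
#' @return A ggplot object.
#' @export
ssd_plot <- function(fit, show_hc5 = TRUE) {
  x <- sort(fit$values)
  n <- length(x)
  pts <- tibble(concentration = x, fraction = (seq_len(n) - 0.5) / n)
  grid <- exp(seq(log(min(x)) - 2, log(max(x)) + 2, length.out = 200))
  curve <- tibble(concentration = grid, fraction = ssd_cdf(fit, grid))
  gg <- ggplot2::ggplot(pts, ggplot2::aes(.data$concentration, .data$fraction)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(paste("Concentration (", mu, "g/L)")),
                  y = "Fraction of species affected",
                  title = sprintf("Species sensitivity distribution (%s)",
                                  fit$family)) +
    ggplot2::theme_minimal()
  if (show_hc5) {
    hc5 <- hc_quantile(fit, 0.05)
    gg <- gg +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed",
                          colour = "grey50") +
      ggplot2::geom_vline(xintercept = hc5, linetype = "dashed",
                          colour = "grey50")
  }
  gg
}
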