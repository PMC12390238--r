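test_that("log-normal MLE is the closed form with divisor n", {
  # frozen oracle: ln-mean and MLE ln-sd of the packaged 12 BPA values,
  # computed independently before the build
  fit <- fit_ssd(bpa_concentrations())
  expect_equal(fit$mu, 6.357075, tolerance = 1e-6)
  expect_equal(fit$sigma, 1.62567, tolerance = 1e-5)
  expect_identical(fit$n, 12L)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$log_likelihood)

  # symmetric ln-values: closed form exactly
  fit2 <- suppressWarnings(fit_ssd(exp(c(0, 2, 4))))
  expect_equal(fit2$mu, 2)
  expect_equal(fit2$sigma, sqrt(8 / 3))
})

test_that("degenerate and invalid inputs are refused", {
  expect_error(suppressWarnings(fit_ssd(c(7, 7, 7))),
               class = "ssdrisk_error_degenerate")
  expect_error(fit_ssd(42), class = "ssdrisk_error_domain")
  expect_error(suppressWarnings(fit_ssd(c(1, -2, 3))),
               class = "ssdrisk_error_domain")
  expect_warning(fit_ssd(c(10, 100, 1000)), "Fewer than 5")
})

test_that("each family's MLE matches a brute-force likelihood search", {
  x <- bpa_concentrations()
  for (fam in c("log_normal", "log_logistic", "log_gumbel")) {
    fit <- fit_ssd(x, fam)
    ref <- brute_force_mle(x, fam)
    expect_equal(fit$mu, ref$mu, tolerance = 1e-4)
    expect_equal(fit$sigma, ref$sigma, tolerance = 1e-4)
    expect_equal(fit$log_likelihood, ref$loglik, tolerance = 1e-6)
  }
})

test_that("log-normal fit agrees with the fitdistrplus cross-check", {
  skip_if_not_installed("fitdistrplus")
  x <- bpa_concentrations()
  fit <- fit_ssd(x)
  ref <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(fit$mu, unname(ref$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(fit$sigma, unname(ref$estimate["sdlog"]), tolerance = 1e-4)
  expect_equal(fit$aic, ref$aic, tolerance = 1e-6)
})

test_that("goodness-of-fit statistics match their defining formulas", {
  x <- bpa_concentrations()
  fit <- fit_ssd(x)
  gof <- gof_statistics(fit, x)
  # frozen golden numbers from an independent brute-force evaluation
  expect_equal(gof$ks_stat, 0.2073692, tolerance = 1e-6)
  expect_equal(gof$ad_stat, 0.4495643, tolerance = 1e-6)

  # re-derive both statistics in-place with independent code
  xs <- sort(x)
  n <- length(xs)
  Fx <- stats::plnorm(xs, fit$mu, fit$sigma)
  ks_ref <- 0
  for (i in seq_len(n)) {
    ks_ref <- max(ks_ref, abs(i / n - Fx[i]), abs(Fx[i] - (i - 1) / n))
  }
  ad_ref <- -n - sum((2 * seq_len(n) - 1) *
                       (log(Fx) + log(1 - rev(Fx)))) / n
  expect_equal(gof$ks_stat, ks_ref)
  expect_equal(gof$ad_stat, ad_ref)
})

test_that("exact fitted quantiles at Hazen positions force KS = 0.5/n", {
  n <- 10
  fit <- ssdrisk:::new_ssd_fit("log_normal", mu = 0, sigma = 1, n = n,
                               log_likelihood = NA_real_)
  x <- stats::qlnorm((seq_len(n) - 0.5) / n)
  gof <- gof_statistics(fit, x)
  expect_equal(gof$ks_stat, 0.5 / n)
})

test_that("AD statistic is finite for tiny samples", {
  fit <- suppressWarnings(fit_ssd(exp(c(1, 3)), "log_normal"))
  expect_true(is.finite(fit$ad_stat))
})

test_that("family selection minimises AIC and picks log-normal on the packaged data", {
  sel <- select_family(bpa_concentrations())
  expect_identical(nrow(sel$table), 3L)
  expect_identical(sel$best$family, "log_normal")
  expect_equal(sel$best$aic, min(sel$table$aic))
  expect_identical(sum(sel$table$aic == min(sel$table$aic)), 1L)
})

test_that("family selection recovers the generating family at large n", {
  x <- withr::with_seed(2024, exp(stats::rnorm(1000, 4, 1.2)))
  sel <- select_family(x)
  expect_identical(sel$best$family, "log_normal")
})

test_that("a single-family candidate list returns that family", {
  sel <- select_family(bpa_concentrations(), families = "log_gumbel")
  expect_identical(sel$best$family, "log_gumbel")
  expect_identical(nrow(sel$table), 1L)
})

test_that("hazard quantiles follow the closed forms", {
  fit <- ssdrisk:::new_ssd_fit("log_normal", 0, 1, 10, NA_real_)
  expect_equal(hc_quantile(fit, 0.5), 1)
  expect_equal(hc_quantile(fit, 0.05), exp(stats::qnorm(0.05)),
               tolerance = 1e-12)
  expect_equal(hc_quantile(fit, 0.05), 0.1930408, tolerance = 1e-6)
  expect_error(hc_quantile(fit, 0), class = "ssdrisk_error_domain")
  expect_error(hc_quantile(fit, 1), class = "ssdrisk_error_domain")

  # packaged data: the HC5 behind the whole assessment
  expect_equal(hc_quantile(fit_ssd(bpa_concentrations()), 0.05),
               39.76893, tolerance = 1e-5)
})

test_that("quantile functions invert the fitted CDF for every family", {
  x <- bpa_concentrations()
  for (fam in c("log_normal", "log_logistic", "log_gumbel")) {
    fit <- fit_ssd(x, fam)
    for (p in c(0.01, 0.05, 0.5, 0.95)) {
      q <- hc_quantile(fit, p)
      expect_equal(ssd_cdf(fit, q), p, tolerance = 1e-9)
      # independent inversion by root finding
      root <- stats::uniroot(function(lx) ssd_cdf(fit, exp(lx)) - p,
                             c(-50, 50), tol = 1e-12)$root
      expect_equal(q, exp(root), tolerance = 1e-6)
    }
  }
})

test_that("hazard quantiles are monotone in p, mu and sigma", {
  p <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  for (fam in c("log_normal", "log_logistic", "log_gumbel")) {
    base <- ssdrisk:::new_ssd_fit(fam, 2, 1, 10, NA_real_)
    expect_true(all(diff(hc_quantile(base, p)) > 0))
    up_mu <- ssdrisk:::new_ssd_fit(fam, 3, 1, 10, NA_real_)
    expect_true(all(hc_quantile(up_mu, p) > hc_quantile(base, p)))
    up_sig <- ssdrisk:::new_ssd_fit(fam, 2, 2, 10, NA_real_)
    lowp <- c(0.01, 0.02)
    expect_true(all(hc_quantile(up_sig, lowp) < hc_quantile(base, lowp)))
  }
})

test_that("fits are scale equivariant: scaling data scales quantiles, not shape or GOF", {
  x <- bpa_concentrations()
  for (fam in c("log_normal", "log_logistic", "log_gumbel")) {
    f1 <- fit_ssd(x, fam)
    f2 <- fit_ssd(x * 37.5, fam)
    expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
    expect_equal(f2$mu, f1$mu + log(37.5), tolerance = 1e-6)
    expect_equal(f2$ks_stat, f1$ks_stat, tolerance = 1e-6)
    expect_equal(f2$ad_stat, f1$ad_stat, tolerance = 1e-6)
    for (p in c(0.05, 0.5)) {
      expect_equal(hc_quantile(f2, p), 37.5 * hc_quantile(f1, p),
                   tolerance = 1e-6)
    }
  }
})
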