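# Shared fixtures built in code. The twelve packaged BPA concentrations are
# read from the installed CSV; tests that need them as a plain vector use
# bpa_concentrations().

bpa_concentrations <- function() {
  read_toxicity_table(ssdrisk_example("bpa_toxicity"))$concentration
}

reference_surrogates <- function() {
  # one representative species per trophic level seeding the ICE coupling
  surrogate_set("BPA", c("Oryzias latipes" = 598,
                         "Daphnia magna" = 5000,
                         "Pseudokirchneriella subcapitata" = 3995))
}

packaged_ice_models <- function() {
  read_ice_models(ssdrisk_example("ice_models"))
}

# brute-force log-likelihood used as an independent oracle against the
# closed-form / optim MLE paths (written on the raw x scale, not ln scale)
brute_force_mle <- function(x, family) {
  dens <- switch(family,
    log_normal = function(x, m, s) stats::dlnorm(x, m, s),
    log_logistic = function(x, m, s) {
      z <- (log(x) - m) / s
      exp(-z) / (s * x * (1 + exp(-z))^2)
    },
    log_gumbel = function(x, m, s) {
      z <- (log(x) - m) / s
      exp(-z - exp(-z)) / (s * x)
    }
  )
  nll <- function(p) -sum(log(dens(x, p[1], exp(p[2]))))
  o <- stats::optim(c(mean(log(x)), log(stats::sd(log(x)))), nll,
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 5000))
  list(mu = o$par[1], sigma = exp(o$par[2]), loglik = -o$value)
}
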