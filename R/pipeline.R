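#' Declarative configuration for a full risk-assessment run
#'
#' Collects every choice the pipeline depends on — there are no hidden
#' defaults downstream: all thresholds are echoed into the run manifest.
#'
#' @param chemical Chemical abbreviation being assessed.
#' @param mode `"experimental"` (fit the SSD to measured records from
#'   `toxicity_table`) or `"in_silico"` (assemble the dataset from
#'   `surrogate_values` and `ice_table` first).
#' @param toxicity_table Path to a chronic toxicity CSV (experimental mode).
#' @param surrogate_values Named numeric vector species -> ug/L
#'   (in-silico mode).
#' @param ice_table Path to the ICE model registry CSV (in-silico mode).
#' @param concentration_table Optional path to a site concentration CSV;
#'   when `NULL` the risk-quotient stage is skipped.
#' @param rules `"default"`, `"table4_compat"`, or a [screening_rules()]
#'   object.
#' @param families SSD families to fit; the AIC-best is selected.
#' @param af Assessment factor in `[1, 5]`.
#' @param p Hazard-concentration proportion (0.05 for HC5).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for every stochastic stage.
#' @param ice_thresholds An [ice_quality_thresholds()] object.
#' @param group_map Named species -> group vector for in-silico records.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(chemical,
                            mode = c("experimental", "in_silico"),
                            toxicity_table = NULL,
                            surrogate_values = NULL,
                            ice_table = NULL,
                            concentration_table = NULL,
                            rules = "default",
                            families = ssd_families,
                            af = 5,
                            p = 0.05,
                            n_boot = 1000,
                            seed = 1,
                            ice_thresholds = ice_quality_thresholds(),
                            group_map = default_group_map()) {
  mode <- match.arg(mode)
  if (mode == "experimental" && is.null(toxicity_table)) {
    abort("Experimental mode requires `toxicity_table`.",
          class = "ssdrisk_error_config")
  }
  if (mode == "in_silico" && (is.null(surrogate_values) || is.null(ice_table))) {
    abort("In-silico mode requires `surrogate_values` and `ice_table`.",
          class = "ssdrisk_error_config")
  }
  if (is.character(rules)) {
    rules <- switch(match.arg(rules, c("default", "table4_compat")),
                    default = screening_rules(),
                    table4_compat = screening_rules_table4_compat())
  }
  structure(
    list(chemical = chemical, mode = mode,
         toxicity_table = toxicity_table,
         surrogate_values = surrogate_values,
         ice_table = ice_table,
         concentration_table = concentration_table,
         rules = rules, families = families, af = af, p = p,
         n_boot = n_boot, seed = seed,
         ice_thresholds = ice_thresholds, group_map = group_map),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments; `surrogate_values` and `group_map` are given as mappings.
#' @return A `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("surrogate_values", "group_map")) {
    if (!is.null(y[[field]])) y[[field]] <- unlist(y[[field]])
  }
  do.call(pipeline_config, y)
}

config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(unclass(config))), tf)
  unname(tools::md5sum(tf))
}

#' Run the full coupled risk-assessment pipeline
#'
#' Orchestrates screen -> (extrapolate) -> fit -> hazard concentration ->
#' PNEC -> per-site risk quotients from one declarative configuration,
#' logging record counts in and out of every stage. Identical
#' configuration and seed reproduce every number exactly.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return An `ssdrisk_report` list: `screening` (counts + rejected
#'   records), `dataset`, `gof_table`, `fit`, `hc`, `pnec`, `risk`,
#'   `manifest`.
#' @export
#' @examples
#' cfg <- pipeline_config(
#'   chemical = "BPA", mode = "experimental",
#'   toxicity_table = ssdrisk_example("bpa_toxicity"),
#'   concentration_table = ssdrisk_example("concentrations"),
#'   rules = "table4_compat", n_boot = 200, seed = 42)
#' report <- run_pipeline(cfg, quiet = TRUE)
#' report$pnec$pnec # ~7.96 ug/L
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "ssdrisk_error_pipeline", parent = e)
    })
  }

  # -- assemble toxicity dataset ------------------------------------------
  dataset_tag <- if (config$mode == "experimental") "experimental" else "in_silico"
  records <- stage("input", {
    if (config$mode == "experimental") {
      read_toxicity_table(config$toxicity_table)
    } else {
      models <- filter_ice_models(read_ice_models(config$ice_table),
                                  config$ice_thresholds)
      build_predicted_dataset(
        surrogate_set(config$chemical, config$surrogate_values),
        models, group_map = config$group_map)
    }
  })
  say("input: %d records (%s mode)", nrow(records), config$mode)

  screened <- stage("screening", screen_records(records, config$rules))
  say("screening: %d retained, %d rejected",
      nrow(screened$retained), nrow(screened$rejected))
  dataset <- stage("aggregation", one_value_per_species(screened$retained))
  say("aggregation: %d species", nrow(dataset))

  # -- SSD fit and hazard concentration -----------------------------------
  sel <- stage("ssd_fit", select_family(dataset$concentration, config$families))
  say("ssd_fit: selected %s (AIC %.2f)", sel$best$family, sel$best$aic)
  hc <- stage("bootstrap", bootstrap_hc(
    dataset$concentration, family = sel$best$family, p = config$p,
    n_boot = config$n_boot, seed = config$seed))
  say("bootstrap: HC%g = %.4g (%.4g-%.4g) ug/L, %d replicates",
      100 * config$p, hc$point, hc$ci_lower, hc$ci_upper, config$n_boot)

  pnec <- stage("pnec", derive_pnec(hc$point, config$af,
                                    chemical = config$chemical,
                                    dataset_tag = dataset_tag))
  say("pnec: %.4g ug/L (AF %g)", pnec$pnec, config$af)

  # -- risk quotients ------------------------------------------------------
  risk <- NULL
  if (!is.null(config$concentration_table)) {
    risk <- stage("risk", {
      conc <- read_concentration_table(config$concentration_table)
      conc <- conc[conc$chemical == config$chemical, , drop = FALSE]
      assess_sites(conc, stats::setNames(pnec$pnec, config$chemical))
    })
    say("risk: %d site records assessed", nrow(risk))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssdrisk")),
    config_md5 = config_fingerprint(config),
    chemical = config$chemical, mode = config$mode,
    seed = config$seed, n_boot = config$n_boot,
    af = config$af, p = config$p,
    families = config$families,
    rules = unclass(config$rules),
    ice_thresholds = unclass(config$ice_thresholds),
    counts = list(input = nrow(records),
                  retained = nrow(screened$retained),
                  rejected = nrow(screened$rejected),
                  species = nrow(dataset),
                  sites = if (is.null(risk)) 0L else nrow(risk))
  )
  structure(
    list(screening = screened, dataset = dataset,
         gof_table = sel$table, fit = sel$best, hc = hc, pnec = pnec,
         risk = risk, manifest = manifest),
    class = "ssdrisk_report"
  )
}

#' @export
print.ssdrisk_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Risk assessment report: %s (%s dataset)\n", m$chemical, m$mode))
  cat(sprintf("  species: %d (from %d input records, %d rejected)\n",
              m$counts$species, m$counts$input, m$counts$rejected))
  cat(sprintf("  SSD: %s, mu = %.4f, sigma = %.4f\n",
              x$fit$family, x$fit$mu, x$fit$sigma))
  cat(sprintf("  HC%g = %.4g ug/L (95%% CI %.4g-%.4g; %d bootstrap reps, seed %d)\n",
              100 * m$p, x$hc$point, x$hc$ci_lower, x$hc$ci_upper,
              m$n_boot, m$seed))
  cat(sprintf("  PNEC = %.4g ug/L (AF = %g)\n", x$pnec$pnec, m$af))
  if (!is.null(x$risk) && nrow(x$risk)) {
    cat(sprintf("  RQ (mean-based): %.3g-%.3g over %d sites; max-based peak %.3g\n",
                min(x$risk$rq_mean), max(x$risk$rq_mean), nrow(x$risk),
                max(x$risk$rq_max)))
  }
  cat(sprintf("  config md5: %s\n", m$config_md5))
  invisible(x)
}
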