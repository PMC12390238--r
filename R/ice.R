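#' Read an ICE model registry
#'
#' Reads a table of interspecies correlation estimation (ICE) models: for
#' each (surrogate, predicted) species pair, the slope and intercept of the
#' log10-linear regression together with its quality metrics. Censored
#' p-values printed as `"<x"` are parsed as their upper bound `x`; the
#' original text is kept in `p_value_label`.
#'
#' @param path CSV with columns `predicted_species`, `surrogate_species`,
#'   `r_squared`, `p_value`, `mse`, `cross_validation_success`, `slope`,
#'   `intercept`.
#' @return An `ice_models` tibble.
#' @export
#' @examples
#' read_ice_models(ssdrisk_example("ice_models"))
read_ice_models <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  required <- c("predicted_species", "surrogate_species", "r_squared",
                "p_value", "mse", "cross_validation_success", "slope",
                "intercept")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", toString(missing)),
          class = "ssdrisk_error_config")
  }
  p_label <- trimws(x$p_value)
  p_num <- suppressWarnings(as.numeric(sub("^<", "", p_label)))
  out <- tibble(
    predicted_species = x$predicted_species,
    surrogate_species = x$surrogate_species,
    r_squared = as.numeric(x$r_squared),
    p_value = p_num,
    p_value_label = p_label,
    mse = as.numeric(x$mse),
    cross_validation_success = as.numeric(x$cross_validation_success),
    slope = as.numeric(x$slope),
    intercept = as.numeric(x$intercept)
  )
  validate_ice_models(out)
}

validate_ice_models <- function(x) {
  if (any(x$r_squared < 0 | x$r_squared > 1, na.rm = TRUE)) {
    abort("r_squared must lie in [0, 1].", class = "ssdrisk_error_domain")
  }
  if (any(x$cross_validation_success < 0 | x$cross_validation_success > 100,
          na.rm = TRUE)) {
    abort("cross_validation_success must lie in [0, 100] percent.",
          class = "ssdrisk_error_domain")
  }
  if (any(!is.finite(x$slope))) {
    abort("slope must be finite.", class = "ssdrisk_error_domain")
  }
  class(x) <- union("ice_models", class(x))
  x
}

#' Predict toxicity for an untested species from a surrogate
#'
#' Evaluates the log10-linear ICE relation
#' `10 ^ (slope * log10(surrogate_value) + intercept)`. Both the surrogate
#' value and the prediction are concentrations in ug/L (the intercept's
#' meaning is tied to this unit convention; see the methods vignette).
#'
#' @param model A one-row `ice_models` tibble (or list with `slope` and
#'   `intercept`).
#' @param surrogate_value Surrogate-species toxicity in ug/L; vectorised.
#' @return Predicted toxicity in ug/L, strictly positive.
#' @export
#' @examples
#' m <- list(slope = 1.01, intercept = -0.14)
#' ice_predict(m, 5000) # ~3944 ug/L
ice_predict <- function(model, surrogate_value) {
  if (any(!is.finite(surrogate_value) | surrogate_value <= 0)) {
    abort("Surrogate toxicity must be finite and strictly positive.",
          class = "ssdrisk_error_domain")
  }
  slope <- model$slope[[1]]
  intercept <- model$intercept[[1]]
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(intercept, "intercept")
  10^(slope * log10(surrogate_value) + intercept)
}

#' Quality thresholds for ICE model selection
#'
#' The default thresholds are the conventional Web-ICE selection
#' guidelines: R-squared above 0.6, mean squared error below 0.95, slope
#' above 0.6, cross-validation success above 60 percent, p-value below
#' 0.01. All comparisons are strict.
#'
#' @param r_squared_min,mse_max,slope_min,cross_validation_min,p_value_max
#'   Threshold values.
#' @return An `ice_quality_thresholds` list.
#' @export
ice_quality_thresholds <- function(r_squared_min = 0.6, mse_max = 0.95,
                                   slope_min = 0.6,
                                   cross_validation_min = 60,
                                   p_value_max = 0.01) {
  structure(
    list(r_squared_min = r_squared_min, mse_max = mse_max,
         slope_min = slope_min, cross_validation_min = cross_validation_min,
         p_value_max = p_value_max),
    class = "ice_quality_thresholds"
  )
}

#' Filter ICE models by quality guidelines
#'
#' @param models An `ice_models` tibble.
#' @param guidelines An [ice_quality_thresholds()] object.
#' @return The subset of `models` passing every threshold.
#' @export
#' @examples
#' ice <- read_ice_models(ssdrisk_example("ice_models"))
#' nrow(filter_ice_models(ice)) # all 6 pass
filter_ice_models <- function(models, guidelines = ice_quality_thresholds()) {
  stopifnot(inherits(guidelines, "ice_quality_thresholds"))
  keep <- models$r_squared > guidelines$r_squared_min &
    models$mse < guidelines$mse_max &
    models$slope > guidelines$slope_min &
    models$cross_validation_success > guidelines$cross_validation_min &
    models$p_value < guidelines$p_value_max
  models[keep & !is.na(keep), , drop = FALSE]
}

#' A set of surrogate-species toxicity values
#'
#' Holds externally obtained toxicity values (e.g. QSAR predictions for one
#' species per trophic level) that seed the ICE extrapolation. The QSAR
#' models themselves are out of scope here: their outputs are inputs.
#'
#' @param chemical Chemical abbreviation.
#' @param values Named numeric vector, species -> concentration in ug/L,
#'   all strictly positive.
#' @return A `surrogate_set` list.
#' @export
#' @examples
#' surrogate_set("BPA", c("Daphnia magna" = 5000, "Oryzias latipes" = 598))
surrogate_set <- function(chemical, values) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    abort("`values` must be a named species -> concentration vector.",
          class = "ssdrisk_error_config")
  }
  if (any(!is.finite(values) | values <= 0)) {
    abort("Surrogate concentrations must be finite and strictly positive.",
          class = "ssdrisk_error_domain")
  }
  structure(list(chemical = chemical, values = values),
            class = "surrogate_set")
}

#' Default species -> taxonomic group map for the packaged ICE registry
#'
#' Covers the three conventional surrogate species and the six predicted
#' species of the packaged model table.
#'
#' @return Named character vector, species -> group.
#' @export
default_group_map <- function() {
  c("Oryzias latipes" = "fish",
    "Pimephales promelas" = "fish",
    "Danio rerio" = "fish",
    "Daphnia magna" = "crustaceans",
    "Ceriodaphnia dubia" = "crustaceans",
    "Daphnia pulex" = "crustaceans",
    "Simocephalus serrulatus" = "crustaceans",
    "Pseudosida ramosa" = "crustaceans",
    "Pseudokirchneriella subcapitata" = "algae",
    "Desmodesmus subspicatus" = "algae")
}

#' Assemble a multi-species predicted toxicity dataset
#'
#' Couples external surrogate toxicity values with the ICE registry: the
#' output contains one record per surrogate species plus one record per
#' applicable model (a model applies when its surrogate is in the set).
#' With three surrogates covering fish, crustaceans and algae and the six
#' packaged models this yields the nine-species dataset used for in-silico
#' SSD fitting. Chained extrapolation (using an ICE prediction as another
#' model's surrogate) is never performed: the models are pairwise
#' calibrations and chaining would compound unquantified error.
#'
#' @param surrogates A [surrogate_set()].
#' @param models An `ice_models` tibble (typically pre-filtered with
#'   [filter_ice_models()]).
#' @param group_map Named character vector species -> group.
#' @param on_missing_surrogate `"warn"` (skip the model with a warning) or
#'   `"error"`.
#' @param duration Duration in days stamped on the synthetic records so
#'   they pass default screening (21 for non-algae; algae records get 4).
#' @return A `toxicity_records` tibble with extra columns `origin`
#'   (`"surrogate"` or `"ice"`) and `ice_surrogate` (the surrogate species
#'   behind each prediction, `NA` for surrogates).
#' @export
#' @examples
#' sur <- surrogate_set("BPA", c(
#'   "Oryzias latipes" = 598, "Daphnia magna" = 5000,
#'   "Pseudokirchneriella subcapitata" = 3995))
#' ice <- read_ice_models(ssdrisk_example("ice_models"))
#' build_predicted_dataset(sur, ice)
build_predicted_dataset <- function(surrogates, models,
                                    group_map = default_group_map(),
                                    on_missing_surrogate = c("warn", "error"),
                                    duration = 21) {
  stopifnot(inherits(surrogates, "surrogate_set"))
  on_missing_surrogate <- match.arg(on_missing_surrogate)

  lookup_group <- function(sp) {
    g <- unname(group_map[sp])
    g[is.na(g)] <- "unknown"
    g
  }

  applicable <- models$surrogate_species %in% names(surrogates$values)
  if (any(!applicable)) {
    msg <- sprintf("%d ICE model(s) skipped: surrogate species absent (%s).",
                   sum(!applicable),
                   toString(unique(models$surrogate_species[!applicable])))
    if (on_missing_surrogate == "error") {
      abort(msg, class = "ssdrisk_error_config")
    }
    warn(msg)
  }
  models <- models[applicable, , drop = FALSE]

  sur_tbl <- tibble(
    species = names(surrogates$values),
    group = lookup_group(names(surrogates$values)),
    endpoint = "NOEC",
    effect_class = "chronic_lethal",
    concentration = unname(surrogates$values),
    duration = duration,
    source = "surrogate",
    provenance_ok = TRUE,
    origin = "surrogate",
    ice_surrogate = NA_character_
  )
  pred_tbl <- tibble(
    species = models$predicted_species,
    group = lookup_group(models$predicted_species),
    endpoint = "NOEC",
    effect_class = "chronic_lethal",
    concentration = purrr::map2_dbl(
      seq_len(nrow(models)), models$surrogate_species,
      function(i, sur) ice_predict(models[i, ], surrogates$values[[sur]])
    ),
    duration = duration,
    source = "ice",
    provenance_ok = TRUE,
    origin = "ice",
    ice_surrogate = models$surrogate_species
  )
  out <- dplyr::bind_rows(sur_tbl, pred_tbl)
  out$duration[out$group == "algae"] <- pmin(duration, 4)
  validate_toxicity_records(out)
}
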