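#' Read a chemical property registry
#'
#' Reads inert physicochemical metadata (molecular weight, solubility,
#' logKow, ...). None of these fields enter any computation downstream; they
#' travel with results for reporting.
#'
#' @param path CSV file with columns `name`, `abbreviation`, `cas_number`,
#'   `molecular_weight` and optional property columns.
#' @return A tibble, one row per chemical.
#' @export
read_chemical_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("name", "abbreviation", "cas_number", "molecular_weight")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", toString(missing)),
          class = "ssdrisk_error_config")
  }
  if (anyDuplicated(x$abbreviation) || any(!nzchar(x$abbreviation))) {
    abort("Chemical abbreviations must be non-empty and unique.",
          class = "ssdrisk_error_config")
  }
  if (any(x$molecular_weight <= 0)) {
    abort("Molecular weights must be positive.", class = "ssdrisk_error_config")
  }
  x
}

toxicity_groups <- c("algae", "crustaceans", "insects", "molluscs",
                     "amphibians", "fish")

#' Construct chronic toxicity records
#'
#' Builds the validated tibble of per-species chronic endpoint records used
#' by screening and SSD fitting. Concentrations are in ug/L, durations in
#' days.
#'
#' @param species Character, binomial species names.
#' @param group Taxonomic group (e.g. `"algae"`, `"fish"`); free text, with
#'   the conventional six groups used by the packaged data.
#' @param concentration Endpoint concentration in ug/L, strictly positive.
#' @param duration Exposure duration in days, strictly positive.
#' @param endpoint Endpoint type; `"NOEC"` is what chronic screening keeps.
#' @param effect_class Effect category; `"chronic_lethal"` passes screening.
#' @param source Free-text provenance label.
#' @param provenance_ok Curator-set flag: `TRUE` when the test followed a
#'   recognised standard protocol. Not computed from the data.
#' @return A `toxicity_records` tibble.
#' @export
#' @examples
#' toxicity_records("Daphnia magna", "crustaceans", 5000, 21)
toxicity_records <- function(species, group, concentration, duration,
                             endpoint = "NOEC",
                             effect_class = "chronic_lethal",
                             source = NA_character_,
                             provenance_ok = TRUE) {
  out <- tibble(
    species = as.character(species),
    group = as.character(group),
    endpoint = as.character(endpoint),
    effect_class = as.character(effect_class),
    concentration = as.numeric(concentration),
    duration = as.numeric(duration),
    source = as.character(source),
    provenance_ok = as.logical(provenance_ok)
  )
  validate_toxicity_records(out)
}

validate_toxicity_records <- function(x) {
  if (any(!is.finite(x$concentration) | x$concentration <= 0)) {
    abort("All concentrations must be finite and strictly positive (ug/L).",
          class = "ssdrisk_error_domain")
  }
  if (any(!is.finite(x$duration) | x$duration <= 0)) {
    abort("All durations must be finite and strictly positive (days).",
          class = "ssdrisk_error_domain")
  }
  class(x) <- union("toxicity_records", class(x))
  x
}

default_toxicity_dialect <- function() {
  list(species = "species", group = "group", endpoint = "endpoint",
       effect_class = "effect_class", concentration = "concentration",
       duration = "duration", source = "source",
       provenance_ok = "provenance_ok")
}

#' Read a chronic toxicity table
#'
#' Reads a delimited table of per-species chronic endpoint concentrations
#' (ug/L). Column names are mapped through a dialect list so that ECOTOX
#' exports and hand-curated tables with different headers can be ingested
#' without editing the file. Rows whose concentration is missing,
#' unparseable or non-positive are rejected and collected into a row-error
#' report attached as the `"row_errors"` attribute (also retrievable with
#' [row_errors()]).
#'
#' @param path CSV/TSV file with a header row.
#' @param dialect Named list mapping canonical names (`species`, `group`,
#'   `endpoint`, `concentration`, `duration`, and optionally `effect_class`,
#'   `source`, `provenance_ok`) to the file's column names. Defaults to the
#'   identity mapping used by the packaged fixtures.
#' @return A `toxicity_records` tibble with a `row_errors` attribute.
#' @export
#' @examples
#' tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
#' nrow(tox)
read_toxicity_table <- function(path, dialect = default_toxicity_dialect()) {
  dialect <- utils::modifyList(default_toxicity_dialect(), dialect)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) {
    abort("Toxicity table is empty.", class = "ssdrisk_error_empty")
  }
  required <- c("species", "group", "endpoint", "concentration", "duration")
  missing <- required[!unlist(dialect[required]) %in% names(raw)]
  if (length(missing)) {
    abort(paste0("Column mapping failed; missing: ",
                 toString(unlist(dialect[missing]))),
          class = "ssdrisk_error_config")
  }
  pick <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  x <- tibble(
    species = pick("species"),
    group = pick("group"),
    endpoint = pick("endpoint"),
    effect_class = pick("effect_class", "chronic_lethal"),
    concentration = suppressWarnings(as.numeric(pick("concentration"))),
    duration = suppressWarnings(as.numeric(pick("duration"))),
    source = pick("source"),
    provenance_ok = as.logical(pick("provenance_ok", "TRUE"))
  )
  x$effect_class[is.na(x$effect_class)] <- "chronic_lethal"
  x$provenance_ok[is.na(x$provenance_ok)] <- TRUE

  bad_conc <- is.na(x$concentration) | x$concentration <= 0
  bad_dur <- is.na(x$duration) | x$duration <= 0
  bad <- bad_conc | bad_dur
  errors <- tibble(
    row = which(bad),
    species = x$species[bad],
    problem = ifelse(bad_conc[bad], "non-positive or unparseable concentration",
                     "non-positive or unparseable duration")
  )
  if (nrow(errors)) {
    warn(sprintf("%d row(s) rejected; see row_errors().", nrow(errors)))
  }
  out <- validate_toxicity_records(x[!bad, , drop = FALSE])
  attr(out, "row_errors") <- errors
  out
}

#' Row-error report collected by a reader
#'
#' @param x An object returned by [read_toxicity_table()].
#' @return A tibble of rejected rows with reasons (zero rows when clean).
#' @export
row_errors <- function(x) {
  attr(x, "row_errors") %||% tibble(row = integer(), species = character(),
                                    problem = character())
}

#' Write chronic toxicity records
#'
#' Inverse of [read_toxicity_table()]; a write-then-read round trip
#' reproduces the record list exactly.
#'
#' @param x A `toxicity_records` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_toxicity_table <- function(x, path) {
  readr::write_csv(as_tibble(unclass_records(x)), path)
  invisible(path)
}

unclass_records <- function(x) {
  attr(x, "row_errors") <- NULL
  class(x) <- setdiff(class(x), c("toxicity_records", "concentration_records"))
  x
}

#' Read a surface-water concentration table
#'
#' Reads per-site min/max/mean concentrations reported in ng/L and converts
#' them to the package's canonical ug/L. Two sentinel tokens are recognised
#' in the concentration columns: `"ND"` (not detected: the record is kept
#' with `detected = FALSE` and all concentrations set to 0) and `"/"` (no
#' data: concentrations become `NA` and `missing_data = TRUE`; such records
#' are excluded from summaries and risk tables).
#'
#' @param path CSV file with columns `location`, `sampling_year` (or `year`),
#'   `chemical`, `conc_min`, `conc_max`, `conc_mean` in ng/L, and optionally
#'   `site_id` and `source`.
#' @return A `concentration_records` tibble with concentrations in ug/L.
#' @export
#' @examples
#' conc <- read_concentration_table(ssdrisk_example("concentrations"))
#' dplyr::filter(conc, location == "Liuxi River", chemical == "BPS")
read_concentration_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) {
    abort("Concentration table is empty.", class = "ssdrisk_error_empty")
  }
  if ("year" %in% names(raw) && !"sampling_year" %in% names(raw)) {
    raw$sampling_year <- raw$year
  }
  required <- c("location", "sampling_year", "chemical",
                "conc_min", "conc_max", "conc_mean")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", toString(missing)),
          class = "ssdrisk_error_config")
  }
  parse_conc <- function(v) {
    v <- trimws(v)
    num <- suppressWarnings(as.numeric(v))
    list(value = num, nd = v == "ND", nodata = v == "/")
  }
  pmin_ <- parse_conc(raw$conc_min)
  pmax_ <- parse_conc(raw$conc_max)
  pmean <- parse_conc(raw$conc_mean)
  nd <- pmin_$nd | pmax_$nd | pmean$nd
  nodata <- (pmin_$nodata | pmax_$nodata | pmean$nodata) & !nd

  conc_min <- ifelse(nd, 0, pmin_$value)
  conc_max <- ifelse(nd, 0, pmax_$value)
  conc_mean <- ifelse(nd, 0, pmean$value)

  x <- tibble(
    site_id = if ("site_id" %in% names(raw)) as.integer(raw$site_id) else seq_len(nrow(raw)),
    location = raw$location,
    sampling_year = as.integer(raw$sampling_year),
    chemical = raw$chemical,
    conc_min = ng_to_ug(conc_min),
    conc_max = ng_to_ug(conc_max),
    conc_mean = ng_to_ug(conc_mean),
    detected = !nd & !nodata,
    missing_data = nodata,
    source = if ("source" %in% names(raw)) raw$source else NA_character_
  )
  bad_order <- x$detected &
    (x$conc_min > x$conc_mean + 1e-12 | x$conc_mean > x$conc_max + 1e-12)
  if (any(bad_order, na.rm = TRUE)) {
    warn(sprintf("%d detected row(s) violate min <= mean <= max; kept verbatim.",
                 sum(bad_order, na.rm = TRUE)))
  }
  neg <- x$detected & (x$conc_min < 0 | x$conc_mean < 0 | x$conc_max < 0)
  if (any(neg, na.rm = TRUE)) {
    abort("Negative concentrations are not allowed.",
          class = "ssdrisk_error_domain")
  }
  class(x) <- union("concentration_records", class(x))
  x
}

#' Write surface-water concentration records
#'
#' Converts back to ng/L and re-emits the `ND` / `/` sentinels so a
#' write-then-read round trip is lossless.
#'
#' @param x A `concentration_records` tibble (ug/L).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(x, path) {
  fmt <- function(v, nd, nodata) {
    out <- as.character(ug_to_ng(v))
    out[nd] <- "ND"
    out[nodata] <- "/"
    out
  }
  nd <- !x$detected & !x$missing_data
  out <- tibble(
    site_id = x$site_id,
    location = x$location,
    sampling_year = x$sampling_year,
    chemical = x$chemical,
    conc_min = fmt(x$conc_min, nd, x$missing_data),
    conc_max = fmt(x$conc_max, nd, x$missing_data),
    conc_mean = fmt(x$conc_mean, nd, x$missing_data),
    source = x$source
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Summarise the occurrence of a chemical across sites
#'
#' Computes the extremes used in occurrence reporting: the smallest reported
#' minimum, the largest reported maximum, and the range of the per-site mean
#' concentrations. Non-detect records contribute zeros; records flagged as
#' having no data are excluded.
#'
#' @param records A `concentration_records` tibble (ug/L).
#' @param chemical Chemical abbreviation to summarise.
#' @return A one-row tibble: `chemical`, `n_sites`, `n_detected`,
#'   `min_of_mins`, `max_of_maxes`, `mean_min`, `mean_max` (all ug/L).
#' @export
#' @examples
#' conc <- read_concentration_table(ssdrisk_example("concentrations"))
#' summarize_occurrence(conc, "BPA")
summarize_occurrence <- function(records, chemical) {
  x <- records[records$chemical == chemical & !records$missing_data, , drop = FALSE]
  if (nrow(x) == 0L) {
    abort(sprintf("No usable records for chemical '%s'.", chemical),
          class = "ssdrisk_error_empty")
  }
  tibble(
    chemical = chemical,
    n_sites = nrow(x),
    n_detected = sum(x$detected),
    min_of_mins = min(x$conc_min),
    max_of_maxes = max(x$conc_max),
    mean_min = min(x$conc_mean),
    mean_max = max(x$conc_mean)
  )
}
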