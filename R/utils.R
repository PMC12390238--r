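#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical internal concentration unit is ug/L; environmental tables arrive
# in ng/L and are converted at the reader boundary only.
ng_to_ug <- function(x) x * 1e-3

ug_to_ng <- function(x) x * 1e3

geometric_mean <- function(x) exp(mean(log(x)))

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ssdrisk_error_domain")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name),
          class = "ssdrisk_error_domain")
  }
  invisible(x)
}

#' Path to a packaged example table
#'
#' The package ships four curated plain-text tables used throughout the
#' documentation and tests: physicochemical properties of the three
#' bisphenols (`"chemicals"`), the registry of interspecies correlation
#' estimation models (`"ice_models"`), surface-water occurrence data for 32
#' Chinese water bodies in ng/L (`"concentrations"`), and the twelve curated
#' chronic NOEC records for bisphenol A in ug/L (`"bpa_toxicity"`).
#'
#' @param table One of `"chemicals"`, `"ice_models"`, `"concentrations"`,
#'   `"bpa_toxicity"`.
#' @return Path to the installed CSV file.
#' @export
#' @examples
#' ssdrisk_example("bpa_toxicity")
ssdrisk_example <- function(table = c("bpa_toxicity", "ice_models",
                                      "concentrations", "chemicals")) {
  table <- match.arg(table)
  file <- switch(table,
    chemicals      = "table1_chemicals.csv",
    ice_models     = "table2_ice_models.csv",
    concentrations = "table3_concentrations.csv",
    bpa_toxicity   = "table4_bpa_toxicity.csv"
  )
  system.file("extdata", file, package = "ssdrisk", mustWork = TRUE)
}
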