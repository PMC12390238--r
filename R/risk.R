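#' Derive a predicted no-effect concentration from an HC5
#'
#' `PNEC = HC5 / AF`, with the assessment factor AF between 1 and 5
#' reflecting residual uncertainty in the dataset behind the SSD.
#'
#' @param hc5 Hazard concentration in ug/L, positive.
#' @param af Assessment factor in `[1, 5]`.
#' @param chemical Optional chemical abbreviation carried into the result.
#' @param dataset_tag `"experimental"` or `"in_silico"`, recording which
#'   kind of toxicity dataset produced the HC5.
#' @param allow_unsafe_af Permit AF outside `[1, 5]` (explicit opt-in).
#' @return A one-row `pnec_result` tibble: `chemical`, `hc5`, `af`, `pnec`,
#'   `dataset_tag` (all concentrations ug/L).
#' @export
#' @examples
#' derive_pnec(39.8, 5, chemical = "BPA") # PNEC 7.96 ug/L
derive_pnec <- function(hc5, af = 5, chemical = NA_character_,
                        dataset_tag = c("experimental", "in_silico"),
                        allow_unsafe_af = FALSE) {
  dataset_tag <- match.arg(dataset_tag)
  stopifnot_scalar_number(hc5, "hc5", positive = TRUE)
  stopifnot_scalar_number(af, "af")
  if (!allow_unsafe_af && (af < 1 || af > 5)) {
    abort("Assessment factor must lie in [1, 5] (set allow_unsafe_af = TRUE to override).",
          class = "ssdrisk_error_domain")
  }
  out <- tibble(chemical = chemical, hc5 = hc5, af = af, pnec = hc5 / af,
                dataset_tag = dataset_tag)
  class(out) <- union("pnec_result", class(out))
  out
}

#' Risk quotient of a measured concentration against a PNEC
#'
#' `RQ = MEC / PNEC`, both in ug/L. Vectorised over `mec`.
#'
#' @param mec Measured environmental concentration(s), ug/L, non-negative.
#' @param pnec Predicted no-effect concentration, ug/L, positive.
#' @return Dimensionless risk quotient(s).
#' @export
#' @examples
#' compute_rq(7.48, 7.96) # ~0.94
compute_rq <- function(mec, pnec) {
  stopifnot_scalar_number(pnec, "pnec", positive = TRUE)
  if (any(!is.finite(mec) | mec < 0)) {
    abort("MEC values must be finite and non-negative.",
          class = "ssdrisk_error_domain")
  }
  mec / pnec
}

rq_tiers <- c("negligible", "low", "moderate", "high")

#' Classify a risk quotient into a risk tier
#'
#' Tier bands: high for `RQ >= 1`, moderate for `0.1 <= RQ < 1`, low for
#' `0.01 <= RQ < 0.1`, and negligible below 0.01. A value of exactly 1 is
#' classified high (the conservative reading of band boundaries that
#' conventionally overlap at 1). The negligible tier extends the
#' conventional three bands downwards rather than stretching "low".
#'
#' @param rq Risk quotient(s), non-negative.
#' @return Ordered factor with levels negligible < low < moderate < high.
#' @export
#' @examples
#' classify_rq(c(0.005, 0.05, 0.5, 1.86))
classify_rq <- function(rq) {
  if (any(!is.finite(rq) | rq < 0)) {
    abort("Risk quotients must be finite and non-negative.",
          class = "ssdrisk_error_domain")
  }
  tier <- ifelse(rq >= 1, "high",
          ifelse(rq >= 0.1, "moderate",
          ifelse(rq >= 0.01, "low", "negligible")))
  factor(tier, levels = rq_tiers, ordered = TRUE)
}

#' Per-site risk quotients against chemical PNECs
#'
#' Computes, for every (site, chemical) record, the risk quotient based on
#' the mean concentration (average case) and on the maximum concentration
#' (most severe case), and classifies both into tiers. Records flagged as
#' having no data are skipped with a warning; non-detect records yield
#' RQ = 0.
#'
#' @param records A `concentration_records` tibble (ug/L).
#' @param pnecs A `pnec_result` tibble (rows from [derive_pnec()], one per
#'   chemical) or a named numeric vector chemical -> PNEC in ug/L.
#' @return A `risk_results` tibble: `site_id`, `location`, `sampling_year`,
#'   `chemical`, `rq_mean`, `rq_max`, `tier_mean`, `tier_max`.
#' @export
#' @examples
#' conc <- read_concentration_table(ssdrisk_example("concentrations"))
#' risk <- assess_sites(conc, c(BPA = 7.96, BPS = 35.2, BPF = 34.2))
#' range(risk$rq_mean[risk$chemical == "BPA"])
assess_sites <- function(records, pnecs) {
  if (inherits(pnecs, "pnec_result") || is.data.frame(pnecs)) {
    pnec_map <- stats::setNames(pnecs$pnec, pnecs$chemical)
  } else {
    pnec_map <- pnecs
  }
  if (nrow(records) == 0L) {
    out <- tibble(site_id = integer(), location = character(),
                  sampling_year = integer(), chemical = character(),
                  rq_mean = numeric(), rq_max = numeric(),
                  tier_mean = classify_rq(numeric()),
                  tier_max = classify_rq(numeric()))
    class(out) <- union("risk_results", class(out))
    return(out)
  }
  need <- unique(records$chemical[!records$missing_data])
  absent <- setdiff(need, names(pnec_map))
  if (length(absent)) {
    abort(paste0("No PNEC supplied for chemical(s): ", toString(absent)),
          class = "ssdrisk_error_config")
  }
  if (any(records$missing_data)) {
    warn(sprintf("%d record(s) with no data skipped.",
                 sum(records$missing_data)))
    records <- records[!records$missing_data, , drop = FALSE]
  }
  pnec <- unname(pnec_map[records$chemical])
  out <- tibble(
    site_id = records$site_id,
    location = records$location,
    sampling_year = records$sampling_year,
    chemical = records$chemical,
    rq_mean = records$conc_mean / pnec,
    rq_max = records$conc_max / pnec
  )
  out$tier_mean <- classify_rq(out$rq_mean)
  out$tier_max <- classify_rq(out$rq_max)
  class(out) <- union("risk_results", class(out))
  out
}

#' Plot per-site risk quotients with tier bands
#'
#' Mean-based RQs as hollow circles and maximum-based RQs as solid
#' circles on a log-scaled axis, with horizontal guides at the tier
#' boundaries 0.01, 0.1 and 1.
#'
#' @param risk A `risk_results` tibble.
#' @return A ggplot object.
#' @export
rq_plot <- function(risk) {
  long <- tidyr::pivot_longer(risk, c("rq_mean", "rq_max"),
                              names_to = "basis", values_to = "rq")
  long$basis <- ifelse(long$basis == "rq_mean", "mean", "max")
  long <- long[long$rq > 0, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(.data$site_id, .data$rq,
                                     shape = .data$basis)) +
    ggplot2::geom_hline(yintercept = c(0.01, 0.1, 1),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::scale_shape_manual(values = c(mean = 1, max = 16)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~chemical) +
    ggplot2::labs(x = "Site", y = "Risk quotient", shape = "MEC basis") +
    ggplot2::theme_minimal()
}
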