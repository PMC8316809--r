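#' Convert per-cell oxygen evolution to biomass-specific carbon fixation
#'
#' Clark-electrode photosynthesis rates come as umol O2 per cell per hour.
#' Dividing by the photosynthetic quotient (mol O2 evolved per mol C fixed)
#' gives umol C per cell per hour; multiplying by 12.011 ug umol^-1 converts
#' to carbon mass; dividing by the cellular carbon quota expresses the rate
#' per unit biomass carbon, i.e. ug C fixed per ug C biomass per hour.
#'
#' @param np_o2 Net photosynthesis (umol O2 cell^-1 h^-1). Vectorised.
#' @param pq Photosynthetic quotient (mol O2 per mol C); default 1.4, a
#'   conventional value for nitrate-grown phytoplankton, configurable.
#' @param carbon_quota Cellular carbon content (ug C cell^-1).
#' @return Biomass-specific net photosynthesis (h^-1).
#' @export
o2_to_specific_carbon <- function(np_o2, pq = 1.4, carbon_quota) {
  if (any(pq <= 0)) abort_domain("pq", "photosynthetic quotient must be > 0")
  if (any(carbon_quota <= 0)) abort_domain("carbon_quota", "must be > 0")
  (np_o2 / pq * 12.011) / carbon_quota
}

#' Carbon demand of observed growth
#'
#' The instantaneous biomass-specific carbon accretion implied by a specific
#' growth rate at fixed carbon quota: `mu / 24`, converting day^-1 to h^-1.
#' (The compounded form `exp(mu/24) - 1` differs by under 2 percent for
#' growth rates up to 1 day^-1.)
#'
#' @param mu Specific growth rate (day^-1). Vectorised.
#' @return Carbon demand of growth (h^-1).
#' @export
growth_carbon_demand <- function(mu) mu / 24

#' Photosynthesis-to-growth carbon budget
#'
#' Expresses net photosynthesis and growth in common carbon units and forms
#' their ratio. A ratio above 1 means the lineage fixes more carbon than its
#' growth demands — surplus photosynthate available for exudation, storage or
#' processes other than division; `surplus_pct = (ratio - 1) * 100`. A ratio
#' at or below 1 (surplus <= 0) does not mean negative photosynthesis: it
#' flags that growth must draw on storage or external carbon
#' (`status = "storage_use"`). Wells with non-positive growth get a null
#' ratio and a reason code, since the budget is undefined there.
#'
#' @param photo Photophysiology table (columns `well_id`, `np_o2`,
#'   `carbon_quota`; optionally `gp_o2`, checked for implied negative
#'   respiration).
#' @param growth Growth table (columns `well_id`, `mu`).
#' @param pq Photosynthetic quotient passed to [o2_to_specific_carbon()].
#' @return Tibble with one row per well: `np_c_specific` and
#'   `growth_c_specific` (both h^-1), `np_growth_ratio`, `surplus_pct`,
#'   `status` (`surplus`, `balanced`, `storage_use` or `undefined`) and
#'   `reason` (non-empty only for undefined budgets).
#' @export
carbon_budget <- function(photo, growth, pq = 1.4) {
  if ("gp_o2" %in% names(photo)) {
    bad <- !is.na(photo$gp_o2) & photo$gp_o2 < photo$np_o2
    if (any(bad))
      warning(sum(bad), " record(s) imply negative respiration (gp_o2 < np_o2)",
              call. = FALSE)
  }
  keys <- intersect(c("focal", "partner", "scenario", "env", "bio_rep",
                      "tech_rep"), names(photo))
  joined <- dplyr::inner_join(
    dplyr::select(photo, dplyr::all_of(c("well_id", keys, "np_o2", "carbon_quota"))),
    dplyr::select(growth, "well_id", "mu"),
    by = "well_id"
  )
  joined |>
    dplyr::mutate(
      np_c_specific = o2_to_specific_carbon(.data$np_o2, pq, .data$carbon_quota),
      growth_c_specific = growth_carbon_demand(.data$mu),
      np_growth_ratio = ifelse(.data$mu > 0,
                               .data$np_c_specific / .data$growth_c_specific,
                               NA_real_),
      surplus_pct = (.data$np_growth_ratio - 1) * 100,
      status = dplyr::case_when(
        .data$mu <= 0 ~ "undefined",
        abs(.data$np_growth_ratio - 1) < 1e-9 ~ "balanced",
        .data$np_growth_ratio > 1 ~ "surplus",
        TRUE ~ "storage_use"
      ),
      reason = ifelse(.data$mu <= 0, "non_positive_growth", "")
    ) |>
    dplyr::select(dplyr::all_of(c("well_id", keys)), "np_c_specific",
                  "growth_c_specific", "np_growth_ratio", "surplus_pct",
                  "status", "reason")
}
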