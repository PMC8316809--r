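#' Two-point specific growth rate
#'
#' The standard batch-culture estimator for exponential, density-independent
#' growth: `mu = (ln(nt) - ln(n0)) / t`, with `n0` the inoculation density,
#' `nt` the density after `t` days. Negative values are permitted (a
#' declining culture); non-positive densities or times are domain errors.
#'
#' @param n0,nt Densities at inoculation and after `t` days (cells ml^-1).
#' @param t Elapsed time (days).
#' @return Specific growth rate (day^-1). Vectorised over all arguments.
#' @export
#' @examples
#' estimate_growth_two_point(100, 1e5, 7) # ~0.987 day^-1
estimate_growth_two_point <- function(n0, nt, t) {
  if (any(!is.finite(n0)) || any(n0 <= 0))
    abort_domain("n0", "densities must be positive and finite")
  if (any(!is.finite(nt)) || any(nt <= 0))
    abort_domain("nt", "densities must be positive and finite")
  if (any(!is.finite(t)) || any(t <= 0))
    abort_domain("t", "elapsed time must be positive")
  (log(nt) - log(n0)) / t
}

#' Log-linear growth rate
#'
#' Regression alternative to the two-point estimator: ordinary least squares
#' of `ln(density)` on time over a whole series, using every observation
#' rather than only the endpoints. With fewer than three points it falls back
#' to the two-point estimator with a warning.
#'
#' @param times Sampling times (days), strictly increasing.
#' @param densities Cell densities (cells ml^-1), all positive.
#' @return A list with `mu` (day^-1), `method`, `t_span` (days) and
#'   `fit_r2` (`NA` for the two-point fallback).
#' @export
estimate_growth_loglinear <- function(times, densities) {
  if (length(times) != length(densities))
    abort_domain("times", "must match densities in length")
  if (any(diff(times) <= 0))
    abort_domain("times", "must be strictly increasing")
  if (any(densities <= 0))
    abort_domain("densities", "must be positive")
  n <- length(times)
  t_span <- times[n] - times[1]
  if (n < 3) {
    warning("fewer than 3 points: falling back to two-point estimator",
            call. = FALSE)
    return(list(mu = estimate_growth_two_point(densities[1], densities[n], t_span),
                method = "two_point", t_span = t_span, fit_r2 = NA_real_))
  }
  fit <- lm(log(densities) ~ times)
  r2 <- suppressWarnings(summary(fit))$r.squared
  list(mu = unname(coef(fit)[2]), method = "log_linear", t_span = t_span,
       fit_r2 = r2)
}

#' Growth rates for a counts table
#'
#' Estimates one specific growth rate per well and series from a tidy counts
#' table. Multi-transfer series are handled per transfer segment (densities
#' reset to the inoculum at each transfer) and the segment estimates averaged,
#' so a 14-day two-transfer assay yields one rate per well. The default
#' method uses the first and last count of each segment; `"loglinear"` fits
#' all points of a segment.
#'
#' @param counts Tidy counts tibble as produced by [simulate_experiment()]
#'   (columns `well_id`, `series`, `transfer`, `day`, `density` plus design
#'   keys). A missing `series` or `transfer` column is treated as a single
#'   series/segment.
#' @param method `"two_point"` (default) or `"loglinear"`.
#' @return Tibble with one row per well and series: design keys, `mu`
#'   (day^-1), `method`, `t_span` and (log-linear only) mean `fit_r2`.
#' @export
estimate_growth <- function(counts, method = c("two_point", "loglinear")) {
  method <- match.arg(method)
  if (!"series" %in% names(counts)) counts$series <- "focal"
  if (!"transfer" %in% names(counts)) counts$transfer <- 1L
  keys <- intersect(c("well_id", "focal", "partner", "scenario", "env",
                      "bio_rep", "tech_rep", "series"), names(counts))
  per_segment <- counts |>
    dplyr::arrange(.data$well_id, .data$series, .data$transfer, .data$day) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "transfer")))) |>
    dplyr::summarise(
      mu = if (method == "two_point" || dplyr::n() < 3) {
        estimate_growth_two_point(dplyr::first(.data$density),
                                  dplyr::last(.data$density),
                                  dplyr::last(.data$day) - dplyr::first(.data$day))
      } else {
        unname(coef(lm(log(.data$density) ~ .data$day))[2])
      },
      t_span = dplyr::last(.data$day) - dplyr::first(.data$day),
      fit_r2 = if (method == "loglinear" && dplyr::n() >= 3)
        suppressWarnings(summary(lm(log(.data$density) ~ .data$day)))$r.squared
      else NA_real_,
      .groups = "drop"
    )
  per_segment |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mu = mean(.data$mu), t_span = sum(.data$t_span),
                     fit_r2 = mean(.data$fit_r2), .groups = "drop") |>
    dplyr::mutate(method = if (method == "two_point") "two_point" else "log_linear")
}
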