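#' Configuration for the regression-to-the-mean null model
#'
#' Growth rates in monoculture and in mixed culture are drawn independently
#' from the same truncated normal distribution over the plausible range for
#' this picoplankter, and the response ratio is computed for each pair.
#' Because the numerator is independent of the denominator, the relationship
#' between monoculture growth and response is L-shaped even though no
#' interaction exists — pure regression to the mean. Defaults: range 0.45 to
#' 1.1 day^-1, mean at the midpoint, standard deviation one sixth of the
#' range (so the untruncated distribution effectively lives inside it).
#'
#' @param mu_min,mu_max Bounds of plausible growth (day^-1).
#' @param n_draws Number of paired draws.
#' @param seed Optional integer seed.
#' @param dist_mean,dist_sd Mean and standard deviation of the (shared)
#'   normal before truncation to `[mu_min, mu_max]`.
#' @return A list of class `null_model_config`.
#' @export
null_model_config <- function(mu_min = 0.45, mu_max = 1.1, n_draws = 1000,
                              seed = NULL,
                              dist_mean = (mu_min + mu_max) / 2,
                              dist_sd = (mu_max - mu_min) / 6) {
  if (mu_min >= mu_max) abort_domain("mu_min", "must be below mu_max")
  if (n_draws < 1) abort_domain("n_draws", "must be >= 1")
  if (dist_sd < 0) abort_domain("dist_sd", "must be >= 0")
  structure(list(mu_min = mu_min, mu_max = mu_max, n_draws = n_draws,
                 seed = seed, dist_mean = dist_mean, dist_sd = dist_sd),
            class = "null_model_config")
}

# Truncated-normal draws by inverse-CDF so draws are a deterministic,
# monotone function of the uniforms.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Mean of the truncated normal by numerical integration (used as the
# reference value for E[mu] under the null configuration).
truncnorm_mean <- function(mean, sd, lo, hi) {
  if (sd == 0) return(mean)
  z <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi)$value
  z / (pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
}

#' Simulate the no-interaction null
#'
#' Draws `n_draws` independent (mu_mono, mu_mixed) pairs from the configured
#' truncated normal, computes the response ratio for each pair, and
#' summarises the induced mono-growth/response relationship by its Spearman
#' rank correlation and per-bin mean responses.
#'
#' @param config A [null_model_config()].
#' @param n_bins Number of equal-count bins for the binned summary.
#' @return A list of class `null_model_result`: `draws` (tibble of
#'   mu_mono, mu_mixed, response), `spearman_rho` (0 with
#'   `degenerate = TRUE` when the distribution is a point mass),
#'   `mean_response`, `binned` (see [binned_null_expectation()]) and the
#'   `config`.
#' @export
simulate_null <- function(config = null_model_config(), n_bins = 10) {
  stopifnot(inherits(config, "null_model_config"))
  run <- function() {
    mu_mono <- rtruncnorm(config$n_draws, config$dist_mean, config$dist_sd,
                          config$mu_min, config$mu_max)
    mu_mixed <- rtruncnorm(config$n_draws, config$dist_mean, config$dist_sd,
                           config$mu_min, config$mu_max)
    tibble::tibble(mu_mono = mu_mono, mu_mixed = mu_mixed,
                   response = compute_response(mu_mixed, mu_mono))
  }
  draws <- if (!is.null(config$seed)) withr::with_seed(config$seed, run())
           else run()
  degenerate <- config$dist_sd == 0 || var(draws$mu_mono) == 0
  rho <- if (degenerate) 0 else
    suppressWarnings(cor(draws$mu_mono, draws$response, method = "spearman"))
  res <- structure(
    list(draws = draws, spearman_rho = rho, degenerate = degenerate,
         mean_response = mean(draws$response), config = config),
    class = "null_model_result"
  )
  res$binned <- binned_null_expectation(res, n_bins)
  res
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "Regression-to-the-mean null: %d draws, Spearman rho = %.3f, mean response = %.3f%s\n",
    nrow(x$draws), x$spearman_rho, x$mean_response,
    if (x$degenerate) " (degenerate point mass)" else ""))
  invisible(x)
}

#' Binned expectation of the null response
#'
#' Splits the draws into equal-count bins of monoculture growth and reports
#' the mean response per bin alongside the analytic expectation
#' `E[mu_mixed] / midpoint(bin)`: under independence the numerator's mean is
#' constant, so the binned means trace a `c / mu` curve — the quantified form
#' of the L-shape.
#'
#' @param result A [simulate_null()] result.
#' @param n_bins Number of bins (>= 1).
#' @return Tibble with one row per bin: `bin`, `mu_lo`, `mu_hi`,
#'   `mu_mid` (midpoint), `n`, `mean_response`, `expected_response` and
#'   `deviation`; empty bins carry `NA` summaries.
#' @export
binned_null_expectation <- function(result, n_bins = 10) {
  stopifnot(inherits(result, "null_model_result"))
  if (n_bins < 1) abort_domain("n_bins", "must be >= 1")
  d <- result$draws
  cfg <- result$config
  e_mixed <- truncnorm_mean(cfg$dist_mean, cfg$dist_sd, cfg$mu_min, cfg$mu_max)
  if (n_bins == 1) {
    breaks <- range(d$mu_mono) + c(-1e-9, 1e-9)
  } else {
    breaks <- unique(stats::quantile(d$mu_mono, probs = seq(0, 1, length.out = n_bins + 1)))
    breaks[1] <- breaks[1] - 1e-9
    breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
    # a (near) point mass collapses the quantiles: fall back to a single bin
    if (length(breaks) < 3) breaks <- range(d$mu_mono) + c(-1e-9, 1e-9)
  }
  idx <- cut(d$mu_mono, breaks, labels = FALSE)
  out <- lapply(seq_len(length(breaks) - 1L), function(b) {
    sel <- which(idx == b)
    mid <- (breaks[b] + breaks[b + 1L]) / 2
    tibble::tibble(
      bin = b, mu_lo = breaks[b], mu_hi = breaks[b + 1L], mu_mid = mid,
      n = length(sel),
      mean_response = if (length(sel) > 0) mean(d$response[sel]) else NA_real_,
      expected_response = e_mixed / mid
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(deviation = .data$mean_response - .data$expected_response)
}

#' Fit the reciprocal null curve
#'
#' Fits `response = c / mu_mono` through the binned means by least squares.
#' Under the no-interaction null the constant `c` estimates the mean mixed-
#' culture growth rate, so comparing `c` with the (numerically integrated)
#' truncated-normal mean checks the whole construction.
#'
#' @param result A [simulate_null()] result.
#' @param n_bins Bins used for the fit.
#' @return A list with `c_hat`, the reference `e_mixed` and their relative
#'   difference `rel_err`.
#' @export
fit_null_curve <- function(result, n_bins = 20) {
  b <- binned_null_expectation(result, n_bins)
  b <- b[!is.na(b$mean_response), ]
  fit <- lm(mean_response ~ 0 + I(1 / mu_mid), data = b)
  c_hat <- unname(coef(fit)[1])
  cfg <- result$config
  e_mixed <- truncnorm_mean(cfg$dist_mean, cfg$dist_sd, cfg$mu_min, cfg$mu_max)
  list(c_hat = c_hat, e_mixed = e_mixed,
       rel_err = abs(c_hat - e_mixed) / e_mixed)
}
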