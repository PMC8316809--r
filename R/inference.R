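#' Fit a (mixed) linear model for growth or response data
#'
#' Wraps `lme4::lmer()` (or `lm()` when no random grouping is requested)
#' behind a declarative spec: an outcome column, fixed-effect terms, and a
#' nesting declaration for the random structure. The conventional nesting
#' treats biological replicate populations as random groups within lineage
#' (`"replicate_in_lineage"`, a random intercept per lineage-replicate
#' population); the reverse declaration (`"lineage_in_replicate"`) is also
#' available. Likelihood-ratio tests of fixed effects require
#' maximum-likelihood fits, so `reml = FALSE` is the default.
#'
#' @param data Data frame with the outcome, fixed-term and grouping columns
#'   (`focal`, `bio_rep` for the built-in nestings).
#' @param outcome Name of the outcome column (absolute growth rate or
#'   response ratio).
#' @param fixed_terms Character vector of fixed-effect terms; empty means
#'   intercept-only.
#' @param random_grouping `"replicate_in_lineage"`, `"lineage_in_replicate"`
#'   or `"none"`.
#' @param reml Use REML instead of ML.
#' @return An object of class `pico_fit`: `loglik`, `n_obs`, `k_params`
#'   (all estimated parameters, variance components included), `aic`,
#'   `aicc`, `coefficients` (tibble with estimates and standard errors),
#'   `converged`, `singular` (a zero random-effect variance is reported, not
#'   hidden), `reml`, `fixed_terms` and the fitted `model`.
#' @export
fit_growth_model <- function(data, outcome,
                             fixed_terms = "focal",
                             random_grouping = c("replicate_in_lineage",
                                                 "lineage_in_replicate",
                                                 "none"),
                             reml = FALSE) {
  random_grouping <- match.arg(random_grouping)
  fixed <- if (length(fixed_terms) == 0) "1" else paste(fixed_terms, collapse = " + ")
  rand <- switch(random_grouping,
                 replicate_in_lineage = "(1 | focal:bio_rep)",
                 lineage_in_replicate = "(1 | bio_rep) + (1 | bio_rep:focal)",
                 none = NULL)
  rhs <- paste(c(fixed, rand), collapse = " + ")
  form <- as.formula(paste(outcome, "~", rhs))

  if (is.null(rand)) {
    model <- lm(form, data = data)
    converged <- TRUE
    singular <- FALSE
    co <- suppressWarnings(summary(model))$coefficients
    coefs <- tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                            se = unname(co[, 2]))
  } else {
    model <- suppressMessages(lme4::lmer(form, data = data, REML = reml))
    msgs <- model@optinfo$conv$lme4$messages
    converged <- is.null(msgs) ||
      !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    singular <- lme4::isSingular(model)
    co <- coef(summary(model))
    coefs <- tibble::tibble(term = rownames(co),
                            estimate = unname(co[, "Estimate"]),
                            se = unname(co[, "Std. Error"]))
  }
  ll <- logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  structure(
    list(loglik = as.numeric(ll), n_obs = n, k_params = k,
         aic = -2 * as.numeric(ll) + 2 * k,
         aicc = aicc(as.numeric(ll), k, n),
         coefficients = coefs, converged = converged, singular = singular,
         reml = reml, fixed_terms = fixed_terms,
         random_grouping = random_grouping,
         formula = deparse(form), model = model),
    class = "pico_fit"
  )
}

#' @export
print.pico_fit <- function(x, ...) {
  cat("Model:", x$formula, "\n")
  cat(sprintf("  logLik %.3f, k %d, n %d, AICc %.2f%s%s\n",
              x$loglik, x$k_params, x$n_obs, x$aicc,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular random effect]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AIC = -2 logLik + 2k`; AICc adds the correction `2k(k+1)/(n - k - 1)`,
#' which vanishes as `n` grows and requires `n > k + 1`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-10, 3, 20) # 27.5
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    abort_domain("n", "AICc is undefined for n <= k + 1")
  aic <- -2 * loglik + 2 * k
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio test for a fixed effect
#'
#' Compares a full model against a reduced model nested inside it:
#' `chi2 = 2 (logLik_full - logLik_reduced)`, degrees of freedom the
#' difference in estimated parameters, p-value from the upper tail of the
#' asymptotic chi-squared distribution. Both fits must be maximum-likelihood
#' (REML likelihoods are not comparable across fixed-effect structures) and
#' converged; a meaningfully negative statistic signals a failed fit and is
#' an error rather than a silent zero.
#'
#' @param full,reduced `pico_fit` objects on the same data, the reduced
#'   model's fixed terms a subset of the full model's.
#' @return A list with `chi2`, `delta_df` and `p`.
#' @export
lrt_fixed_effect <- function(full, reduced) {
  stopifnot(inherits(full, "pico_fit"), inherits(reduced, "pico_fit"))
  if (full$reml || reduced$reml)
    stop("likelihood-ratio tests require maximum-likelihood fits (reml = FALSE)",
         call. = FALSE)
  if (!full$converged || !reduced$converged)
    stop("refusing a likelihood-ratio test on a non-converged fit", call. = FALSE)
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted to different numbers of observations", call. = FALSE)
  if (!all(reduced$fixed_terms %in% full$fixed_terms) ||
      full$k_params < reduced$k_params)
    stop("reduced model is not nested in the full model", call. = FALSE)
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -1e-8)
    stop("negative likelihood-ratio statistic: refit the models", call. = FALSE)
  chi2 <- max(chi2, 0)
  delta_df <- full$k_params - reduced$k_params
  # identical specifications: a degenerate comparison, nothing to reject
  p <- if (delta_df == 0) 1 else pchisq(chi2, df = delta_df, lower.tail = FALSE)
  list(chi2 = chi2, delta_df = delta_df, p = p)
}

#' Reactiveness as a function of surplus photosynthate
#'
#' Joins response records to monoculture carbon budgets and asks, scenario by
#' scenario, whether lineages with more surplus photosynthate react more
#' strongly to conspecific cues. For each scenario (and environment) a model
#' with the surplus predictor and an intercept-only model are fitted by
#' maximum likelihood with the declared random nesting, and the one with the
#' smaller AICc is selected.
#'
#' @param responses Response records from
#'   [pair_treatment_with_monoculture()].
#' @param budgets Carbon budgets from [carbon_budget()] for monoculture
#'   wells; aggregated to one value per lineage, environment and biological
#'   replicate before joining.
#' @param predictor Budget column to use (`"surplus_pct"` or
#'   `"np_growth_ratio"`).
#' @param random_grouping Passed to [fit_growth_model()].
#' @param min_lineages Scenarios with fewer focal lineages are skipped with
#'   a message.
#' @return A list with `results` (tibble: scenario, env, n, slope, se,
#'   aicc_full, aicc_null, best_model) and `fits` (named list of the full
#'   `pico_fit` objects).
#' @export
fit_reactiveness_model <- function(responses, budgets,
                                   predictor = "surplus_pct",
                                   random_grouping = "replicate_in_lineage",
                                   min_lineages = 3) {
  mono_budget <- budgets |>
    dplyr::filter(is.na(.data$reason) | .data$reason == "") |>
    dplyr::group_by(.data$focal, .data$env, .data$bio_rep) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(predictor), mean),
                     .groups = "drop")
  joined <- dplyr::inner_join(responses, mono_budget,
                              by = c("focal", "env", "bio_rep"))
  groups <- joined |> dplyr::distinct(.data$scenario, .data$env)
  fits <- list()
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sc <- groups$scenario[i]; ev <- groups$env[i]
    d <- dplyr::filter(joined, .data$scenario == sc, .data$env == ev)
    if (dplyr::n_distinct(d$focal) < min_lineages) {
      message("skipping scenario ", sc, " (", ev, "): fewer than ",
              min_lineages, " lineages")
      return(NULL)
    }
    full <- fit_growth_model(d, "response", fixed_terms = predictor,
                             random_grouping = random_grouping)
    null <- fit_growth_model(d, "response", fixed_terms = character(),
                             random_grouping = random_grouping)
    fits[[paste(sc, ev, sep = ".")]] <<- full
    slope_row <- full$coefficients[full$coefficients$term == predictor, ]
    tibble::tibble(
      scenario = sc, env = ev, n = nrow(d),
      slope = slope_row$estimate, se = slope_row$se,
      aicc_full = full$aicc, aicc_null = null$aicc,
      best_model = ifelse(full$aicc < null$aicc, "with_predictor",
                          "intercept_only")
    )
  })
  list(results = dplyr::bind_rows(rows), fits = fits)
}
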