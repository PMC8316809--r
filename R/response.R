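#' Mono- versus mixed-culture response ratio
#'
#' The response of a focal lineage to a social cue is its growth rate in the
#' treatment divided by its growth rate alone. A response of 1 means no
#' difference; values above 1 mean faster growth in mixed culture, below 1
#' slower. The ratio is scale-invariant: rescaling both rates by the same
#' positive factor leaves it unchanged.
#'
#' @param mu_treatment Growth rate in the treatment (day^-1).
#' @param mu_alone Growth rate of the same lineage alone (day^-1); must be
#'   non-zero.
#' @return The response ratio (dimensionless). Vectorised.
#' @export
compute_response <- function(mu_treatment, mu_alone) {
  if (any(mu_alone == 0))
    abort_domain("mu_alone", "monoculture growth rate must be non-zero")
  mu_treatment / mu_alone
}

#' Pair treatment wells with their monoculture controls
#'
#' Builds one response record per focal lineage, partner, scenario,
#' environment and biological replicate. Technical replicates are averaged
#' first; biological replicates remain the inferential unit. Each treatment
#' (non-self pair) is matched to the scenario's self-pair control for the
#' same focal lineage, environment and biological replicate where one exists,
#' falling back to the plain monoculture mean otherwise. Records with no
#' control are skipped with a message.
#'
#' @param growth Growth table from [estimate_growth()] (columns `focal`,
#'   `partner`, `scenario`, `env`, `bio_rep`, `mu`; a `series` column, if
#'   present, is filtered to the focal series).
#' @return Tibble of response records: design keys, `mu_treatment`,
#'   `mu_alone`, `control` (`"self_pair"` or `"monoculture"`), `response`
#'   and a `flag` column marking negative growth rates.
#' @export
pair_treatment_with_monoculture <- function(growth) {
  if ("series" %in% names(growth))
    growth <- dplyr::filter(growth, .data$series == "focal")
  by_bio <- growth |>
    dplyr::group_by(.data$focal, .data$partner, .data$scenario, .data$env,
                    .data$bio_rep) |>
    dplyr::summarise(mu = mean(.data$mu), .groups = "drop")

  mono <- by_bio |>
    dplyr::filter(.data$scenario == "monoculture") |>
    dplyr::select("focal", "env", "bio_rep", mu_mono = "mu")
  selfpair <- by_bio |>
    dplyr::filter(.data$scenario != "monoculture",
                  !is.na(.data$partner), .data$partner == .data$focal) |>
    dplyr::select("focal", "scenario", "env", "bio_rep", mu_self = "mu")

  treat <- by_bio |>
    dplyr::filter(.data$scenario != "monoculture",
                  !is.na(.data$partner), .data$partner != .data$focal) |>
    dplyr::rename(mu_treatment = "mu") |>
    dplyr::left_join(selfpair, by = c("focal", "scenario", "env", "bio_rep")) |>
    dplyr::left_join(mono, by = c("focal", "env", "bio_rep")) |>
    dplyr::mutate(
      control = dplyr::case_when(!is.na(.data$mu_self) ~ "self_pair",
                                 !is.na(.data$mu_mono) ~ "monoculture",
                                 TRUE ~ NA_character_),
      mu_alone = dplyr::coalesce(.data$mu_self, .data$mu_mono)
    )

  dropped <- dplyr::filter(treat, is.na(.data$mu_alone))
  if (nrow(dropped) > 0)
    message("skipping ", nrow(dropped),
            " record(s) with no monoculture or self-pair control: ",
            paste(utils::head(unique(dropped$focal), 5), collapse = ", "))
  treat |>
    dplyr::filter(!is.na(.data$mu_alone), .data$mu_alone != 0) |>
    dplyr::mutate(
      response = compute_response(.data$mu_treatment, .data$mu_alone),
      flag = ifelse(.data$mu_treatment < 0 | .data$mu_alone < 0,
                    "negative_growth", "")
    ) |>
    dplyr::select("focal", "partner", "scenario", "env", "bio_rep",
                  "mu_treatment", "mu_alone", "control", "response", "flag")
}

#' Within- and between-lineage variance of growth
#'
#' Quantifies how variable growth rates are within lineages (mean over
#' lineages of the sample variance across biological replicates, technical
#' replicates averaged first) and between lineages (sample variance of
#' lineage mean growth), per environment. When both ambient and elevated
#' environments are present, the elevated-to-ambient fold changes of both
#' components are reported, the contrast used to ask whether an ameliorated
#' environment broadens the spread of growth strategies.
#'
#' @param growth Growth table (columns `focal`, `env`, `bio_rep`, `mu`;
#'   technical replicates, if present as multiple rows, are averaged).
#' @return A list of class `variance_summary` with `by_env` (tibble: env,
#'   within_lineage_var, between_lineage_var, n_lineages) and, when both
#'   environments are present, `fold_within` and `fold_between`
#'   (elevated / ambient).
#' @export
variance_components <- function(growth) {
  per_rep <- growth |>
    dplyr::group_by(.data$focal, .data$env, .data$bio_rep) |>
    dplyr::summarise(mu = mean(.data$mu), .groups = "drop")
  singletons <- per_rep |>
    dplyr::count(.data$focal, .data$env) |>
    dplyr::filter(.data$n < 2)
  if (nrow(singletons) > 0)
    message(nrow(singletons),
            " lineage(s) with a single replicate contribute nothing to the within-lineage component")
  by_env <- per_rep |>
    dplyr::group_by(.data$env, .data$focal) |>
    dplyr::summarise(rep_var = if (dplyr::n() >= 2) var(.data$mu) else NA_real_,
                     lin_mean = mean(.data$mu), .groups = "drop") |>
    dplyr::group_by(.data$env) |>
    dplyr::summarise(
      within_lineage_var = mean(.data$rep_var, na.rm = TRUE),
      between_lineage_var = var(.data$lin_mean),
      n_lineages = dplyr::n(), .groups = "drop"
    )
  out <- list(by_env = by_env)
  if (all(c("ambient", "elevated") %in% by_env$env)) {
    amb <- by_env[by_env$env == "ambient", ]
    ele <- by_env[by_env$env == "elevated", ]
    out$fold_within <- ele$within_lineage_var / amb$within_lineage_var
    out$fold_between <- ele$between_lineage_var / amb$between_lineage_var
  }
  structure(out, class = "variance_summary")
}

#' @export
print.variance_summary <- function(x, ...) {
  print(x$by_env)
  if (!is.null(x$fold_between))
    cat(sprintf("fold (elevated/ambient): between %.2f, within %.2f\n",
                x$fold_between, x$fold_within))
  invisible(x)
}
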