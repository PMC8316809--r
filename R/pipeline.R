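#' Write a pipeline table with a metadata sidecar
#'
#' All pipeline outputs are tidy CSV files accompanied by a small JSON
#' sidecar recording the package version, the master seed and the key
#' generator parameters, so any table can be regenerated exactly. Sidecars
#' contain no timestamps: identical inputs give byte-identical outputs.
#'
#' @param x Data frame to write.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#' @param meta Named list of metadata to record.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(x, path, meta = list()) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- c(list(file = basename(path),
                 package = "picosocial",
                 version = as.character(packageVersion("picosocial")),
                 n_rows = nrow(x)),
            meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline table
#'
#' @param path CSV path written by [write_pipeline_csv()] (or any tidy CSV
#'   matching the pipeline schemas).
#' @return A tibble.
#' @export
read_pipeline_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Run the whole analysis pipeline
#'
#' Chains every stage under one master seed: draws paper-like lineage panels
#' for both pCO2 environments, simulates the full-factorial experiment
#' (monoculture, membrane-insert, supernatant-spike and direct co-culture
#' scenarios), estimates growth rates, pairs treatments with their controls
#' to form response ratios, summarises within- and between-lineage variance,
#' computes carbon budgets, runs the regression-to-the-mean null model,
#' tests the lineage effect on growth by likelihood ratio per scenario and
#' environment, and fits the reactiveness-versus-surplus model. When
#' `out_dir` is given, every table is written as CSV with a metadata
#' sidecar; reruns with the same seed are byte-identical.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory (created if needed).
#' @param n_lineages Lineages per environment panel.
#' @param n_bio,n_tech Replicate structure.
#' @param duration_days Assay length in days.
#' @param scenarios Scenarios to simulate.
#' @param null_draws Number of draws for the null model.
#' @param pq Photosynthetic quotient for the carbon budgets.
#' @return A named list with `counts`, `photo`, `growth`, `responses`,
#'   `variance`, `budgets`, `null`, `lineage_lrt` and `reactiveness`.
#' @export
run_pipeline <- function(seed = 1L, out_dir = NULL, n_lineages = 6,
                         n_bio = 3, n_tech = 3, duration_days = 7,
                         scenarios = SCENARIOS, null_draws = 1000,
                         pq = 1.4) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4L))

  experiments <- lapply(seq_along(c("ambient", "elevated")), function(i) {
    env <- c("ambient", "elevated")[i]
    panel <- withr::with_seed(seeds[1] %% 2e9 + i,
                              paper_like_lineages(n_lineages, env = env))
    design <- experiment_design(panel, scenarios = scenarios, n_bio = n_bio,
                                n_tech = n_tech, duration_days = duration_days,
                                seed = (seeds[2] %% 2e9) + i)
    simulate_experiment(design, pq = pq)
  })
  counts <- dplyr::bind_rows(lapply(experiments, function(e) e$counts))
  photo <- dplyr::bind_rows(lapply(experiments, function(e) e$photo))

  growth <- estimate_growth(counts)
  responses <- pair_treatment_with_monoculture(growth)
  mono_growth <- dplyr::filter(growth, .data$scenario == "monoculture",
                               .data$series == "focal")
  variance <- variance_components(mono_growth)
  budgets <- carbon_budget(dplyr::filter(photo, .data$scenario == "monoculture"),
                           growth, pq = pq)
  null <- simulate_null(null_model_config(n_draws = null_draws,
                                          seed = seeds[3] %% 2e9))

  lrt <- growth |>
    dplyr::filter(.data$series == "focal") |>
    dplyr::group_by(.data$scenario, .data$env) |>
    dplyr::group_map(function(d, key) {
      full <- fit_growth_model(d, "mu", fixed_terms = "focal")
      red <- fit_growth_model(d, "mu", fixed_terms = character())
      t <- lrt_fixed_effect(full, red)
      tibble::tibble(scenario = key$scenario, env = key$env,
                     chi2 = t$chi2, delta_df = t$delta_df, p = t$p)
    }) |>
    dplyr::bind_rows()

  reactiveness <- fit_reactiveness_model(responses, budgets)

  out <- list(counts = counts, photo = photo, growth = growth,
              responses = responses, variance = variance, budgets = budgets,
              null = null, lineage_lrt = lrt,
              reactiveness = reactiveness$results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(seed = seed, n_lineages = n_lineages, n_bio = n_bio,
                 n_tech = n_tech, duration_days = duration_days,
                 scenarios = scenarios, null_draws = null_draws, pq = pq)
    write_pipeline_csv(counts, file.path(out_dir, "counts.csv"), meta)
    write_pipeline_csv(photo, file.path(out_dir, "photophysiology.csv"), meta)
    write_pipeline_csv(growth, file.path(out_dir, "growth.csv"), meta)
    write_pipeline_csv(responses, file.path(out_dir, "responses.csv"), meta)
    write_pipeline_csv(variance$by_env, file.path(out_dir, "variance.csv"),
                       c(meta, list(fold_between = variance$fold_between,
                                    fold_within = variance$fold_within)))
    write_pipeline_csv(budgets, file.path(out_dir, "budgets.csv"), meta)
    write_pipeline_csv(null$draws, file.path(out_dir, "null_draws.csv"), meta)
    write_pipeline_csv(null$binned, file.path(out_dir, "null_binned.csv"),
                       c(meta, list(spearman_rho = null$spearman_rho,
                                    mean_response = null$mean_response)))
    write_pipeline_csv(lrt, file.path(out_dir, "lineage_lrt.csv"), meta)
    write_pipeline_csv(reactiveness$results,
                       file.path(out_dir, "reactiveness.csv"), meta)
  }
  invisible(out)
}
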