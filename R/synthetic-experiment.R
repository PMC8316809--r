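#' Define a lineage profile
#'
#' A lineage (strain) is a set of cells related by descent that share a
#' phenotype under identical conditions. A profile collects the parameters the
#' generator needs to emulate one lineage in one evolutionary environment:
#' its intrinsic monoculture growth rate, how it modulates growth under each
#' social-milieu scenario, its biomass-specific net photosynthesis and cellular
#' carbon quota, and the replicate-level noise magnitudes.
#'
#' @param lineage_id Character label for the lineage.
#' @param env Evolutionary/assay environment, `"ambient"` or `"elevated"`
#'   pCO2.
#' @param mu_mono Intrinsic monoculture growth rate (day^-1), must be > 0.
#' @param reactiveness Named numeric vector of multiplicative growth
#'   modulators, one per paired scenario (`thincert`, `spike`, `direct`). A
#'   value of 1 means the lineage ignores that cue; values are applied only
#'   for non-self partners (self-pairs and monoculture are always 1). All
#'   values must be > 0 so growth rates stay positive.
#' @param np_specific Biomass-specific net photosynthesis (h^-1, carbon
#'   fixed per carbon biomass per hour). Default places the NP-to-growth
#'   ratio at 1.92, a typical ambient-pCO2 calibration.
#' @param carbon_quota Cellular carbon content (ug C cell^-1).
#' @param cv_bio,cv_tech Coefficients of variation of the multiplicative
#'   lognormal noise attached to biological replicate populations (shared
#'   within a replicate) and to individual technical observations.
#'
#' @return A one-row tibble with one column per field.
#' @export
lineage_profile <- function(lineage_id, env = c("ambient", "elevated"),
                            mu_mono,
                            reactiveness = c(thincert = 1, spike = 1, direct = 1),
                            np_specific = 1.92 * mu_mono / 24,
                            carbon_quota = 1.5e-7,
                            cv_bio = 0.10, cv_tech = 0.05) {
  env <- match.arg(env)
  if (!is.numeric(mu_mono) || length(mu_mono) != 1L || mu_mono <= 0)
    abort_domain("mu_mono", "must be a single positive growth rate (day^-1)")
  if (carbon_quota <= 0) abort_domain("carbon_quota", "must be > 0")
  if (cv_bio < 0 || cv_tech < 0) abort_domain("cv_bio/cv_tech", "must be >= 0")
  react <- reactiveness[PAIRED_SCENARIOS]
  if (anyNA(react))
    abort_domain("reactiveness",
                 "must be named with values for thincert, spike and direct")
  if (any(react <= 0))
    abort_domain("reactiveness", "all multipliers must be > 0")
  tibble::tibble(
    lineage_id = as.character(lineage_id), env = env, mu_mono = mu_mono,
    react_thincert = unname(react["thincert"]),
    react_spike = unname(react["spike"]),
    react_direct = unname(react["direct"]),
    np_specific = np_specific, carbon_quota = carbon_quota,
    cv_bio = cv_bio, cv_tech = cv_tech
  )
}

#' Reactiveness under a regression-to-range rule
#'
#' Builds per-scenario growth multipliers that pull a lineage's growth rate
#' towards the midpoint of the viable range: slow growers speed up and fast
#' growers slow down, the pattern repeatedly seen when lineages meet non-self
#' conspecifics. The multiplier is `(target_mid / mu_mono)^gamma`, so
#' `gamma = 0` means no reaction and `gamma = 1` full convergence on the
#' midpoint.
#'
#' @param mu_mono Monoculture growth rate (day^-1).
#' @param target_mid Midpoint of the viable growth range (day^-1).
#' @param gamma Convergence strength in `[0, 1]`; either a single value or a
#'   named vector over `thincert`, `spike`, `direct`.
#' @return Named numeric vector of multipliers for the three paired scenarios.
#' @export
reactiveness_regression_to_range <- function(mu_mono, target_mid = 0.775,
                                             gamma = 0.5) {
  if (any(gamma < 0 | gamma > 1)) abort_domain("gamma", "must lie in [0, 1]")
  if (length(gamma) == 1L) gamma <- setNames(rep(gamma, 3L), PAIRED_SCENARIOS)
  gamma <- gamma[PAIRED_SCENARIOS]
  if (anyNA(gamma)) abort_domain("gamma", "must cover thincert, spike, direct")
  setNames((target_mid / mu_mono)^gamma, PAIRED_SCENARIOS)
}

#' Paper-like lineage panels
#'
#' Draws a panel of lineage profiles calibrated to the study system: ambient
#' monoculture growth rates inside the plausible range for this picoplankter
#' (0.45 to 1.1 day^-1), elevated-pCO2 panels with faster mean growth, a
#' configurable fold increase in between-lineage variance under elevation,
#' response damping at elevated pCO2, and NP set so that photosynthetic carbon
#' fixation exceeds the carbon demand of growth by a configurable ratio.
#'
#' @param n_lineages Number of lineages in the panel.
#' @param env `"ambient"` or `"elevated"`.
#' @param mean_mu Mean monoculture growth rate for the panel (day^-1).
#'   Defaults to 0.7 (ambient) or 0.85 (elevated).
#' @param sd_mu Between-lineage standard deviation of growth at ambient
#'   pCO2 (day^-1).
#' @param fold_between Fold increase of between-lineage *variance* under
#'   elevated relative to ambient pCO2.
#' @param gamma Regression-to-range strength per scenario (see
#'   [reactiveness_regression_to_range()]); graded so the direct cue elicits
#'   the strongest response and the supernatant spike the weakest.
#' @param damping Target fold reduction of the panel-mean response magnitude
#'   (mean absolute log response) for elevated relative to ambient panels.
#'   Elevated lineages spread over a wider growth range, which by itself
#'   would inflate regression-to-range responses, so the log-multipliers are
#'   shrunk by a factor calibrated (by numerical integration over the two
#'   truncated growth distributions) to leave elevated responses `damping`
#'   times weaker than ambient ones on average.
#' @param np_ratio Target mean NP-to-growth carbon ratio for the panel.
#'   Biomass-specific NP is set at the panel level
#'   (`np_ratio * mean_mu / 24` for every lineage), so slow growers carry a
#'   larger surplus of photosynthate than fast growers — the allocation
#'   pattern that makes surplus predictive of reactiveness.
#' @param truncate If `TRUE`, clamp drawn growth rates to `[0.45, 1.1]`
#'   day^-1 (the plausible range); turn off when planting variance
#'   structures that the clamp would distort.
#' @param cv_bio,cv_tech Replicate noise CVs passed to [lineage_profile()].
#' @return Tibble of lineage profiles (one row per lineage).
#' @export
paper_like_lineages <- function(n_lineages = 6, env = c("ambient", "elevated"),
                                mean_mu = NULL, sd_mu = 0.12,
                                fold_between = 3.9,
                                gamma = c(thincert = 0.5, spike = 0.3, direct = 0.7),
                                damping = 1.3, np_ratio = 1.92,
                                truncate = TRUE,
                                cv_bio = 0.10, cv_tech = 0.05) {
  env <- match.arg(env)
  mean_mu <- mean_mu %||% if (env == "ambient") 0.7 else 0.85
  sdev <- if (env == "elevated") sd_mu * sqrt(fold_between) else sd_mu
  mu <- if (truncate) rtruncnorm(n_lineages, mean_mu, sdev, 0.45, 1.1)
        else pmax(rnorm(n_lineages, mean_mu, sdev), 0.05)
  shrink <- if (env == "elevated")
    damping_shrinkage(0.7, sd_mu, mean_mu, sdev, damping) else 1
  dplyr::bind_rows(lapply(seq_len(n_lineages), function(i) {
    react <- reactiveness_regression_to_range(mu[i], gamma = gamma)
    react <- react^shrink
    lineage_profile(sprintf("L%02d", i), env = env, mu_mono = mu[i],
                    reactiveness = react,
                    np_specific = np_ratio * mean_mu / 24,
                    cv_bio = cv_bio, cv_tech = cv_tech)
  }))
}

#' Specify an experiment design
#'
#' Lays out a semi-continuous batch-culture experiment: which social-milieu
#' scenarios are run, which lineages take part, the replicate structure, the
#' sampling schedule and the inoculation density. Paired scenarios use
#' full-factorial ordered lineage pairings including self-pairs, which act as
#' the scenario-specific controls.
#'
#' @param lineages Tibble of lineage profiles (rows from [lineage_profile()]).
#' @param scenarios Subset of `monoculture`, `thincert`, `spike`, `direct`.
#' @param n_bio,n_tech Numbers of biological and technical replicates
#'   (default 3 and 3, the standard layout for this assay).
#' @param duration_days Length of one assay (days); daily sampling.
#' @param transfer_days Optional days at which cultures are transferred
#'   (re-diluted to the inoculum), e.g. `7` for a 14-day two-transfer direct
#'   assay. Densities restart from the inoculum after each transfer.
#' @param inoculum Inoculation density (cells ml^-1), default 100.
#' @param mu_ceiling Plausibility ceiling on effective growth rates
#'   (day^-1); designs implying faster growth are rejected.
#' @param seed Integer seed; echoed into all outputs.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(lineages, scenarios = SCENARIOS,
                              n_bio = 3, n_tech = 3, duration_days = 7,
                              transfer_days = NULL, inoculum = 100,
                              mu_ceiling = 3, seed = 1L) {
  scenarios <- match.arg(scenarios, SCENARIOS, several.ok = TRUE)
  if (duration_days <= 0) abort_domain("duration_days", "must be positive")
  if (inoculum <= 0) abort_domain("inoculum", "must be positive")
  if (n_bio < 1 || n_tech < 1) abort_domain("n_bio/n_tech", "must be >= 1")
  if (!is.null(transfer_days) &&
      (any(transfer_days <= 0) || any(transfer_days >= duration_days)))
    abort_domain("transfer_days", "must fall strictly inside the assay")
  stopifnot(is.data.frame(lineages), nrow(lineages) >= 1)
  structure(
    list(lineages = lineages, scenarios = scenarios, n_bio = n_bio,
         n_tech = n_tech, duration_days = duration_days,
         transfer_days = sort(unique(transfer_days)), inoculum = inoculum,
         mu_ceiling = mu_ceiling, seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", nrow(x$lineages), "lineages,",
      paste(x$scenarios, collapse = "/"), "\n")
  cat("  replicates:", x$n_bio, "biological x", x$n_tech, "technical;",
      x$duration_days, "days; inoculum", x$inoculum, "cells/ml; seed",
      x$seed, "\n")
  invisible(x)
}

# Exponent that shrinks elevated-panel log-multipliers so the expected
# magnitude of log(mid / mu) — and with it the mean absolute log response —
# lands `damping` times below the ambient panel's, despite the wider
# elevated growth distribution. Expectations over the truncated normals by
# numerical integration; target midpoint 0.775 day^-1, range 0.45-1.1.
damping_shrinkage <- function(mean_amb, sd_amb, mean_elev, sd_elev, damping,
                              mid = 0.775, lo = 0.45, hi = 1.1) {
  e_abs_log <- function(mean, sd) {
    z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
    stats::integrate(function(x) abs(log(mid / x)) * stats::dnorm(x, mean, sd),
                     lo, hi)$value / z
  }
  e_abs_log(mean_amb, sd_amb) / (damping * e_abs_log(mean_elev, sd_elev))
}

# Enumerate wells: monoculture wells have no partner; paired scenarios use
# every ordered focal x partner combination including self-pairs.
design_wells <- function(design) {
  ids <- design$lineages$lineage_id
  reps <- tidyr::expand_grid(bio_rep = seq_len(design$n_bio),
                             tech_rep = seq_len(design$n_tech))
  per_scenario <- lapply(design$scenarios, function(sc) {
    if (sc == "monoculture") {
      grid <- tidyr::expand_grid(focal = ids, partner = NA_character_)
    } else {
      grid <- tidyr::expand_grid(focal = ids, partner = ids)
    }
    tidyr::expand_grid(grid, reps) |> dplyr::mutate(scenario = sc)
  })
  wells <- dplyr::bind_rows(per_scenario)
  env <- design$lineages$env[match(wells$focal, design$lineages$lineage_id)]
  wells |>
    dplyr::mutate(
      env = env,
      well_id = sprintf("%s_%s_%s_%s_b%d_t%d", .data$scenario, .data$env,
                        .data$focal,
                        ifelse(is.na(.data$partner), "none", .data$partner),
                        .data$bio_rep, .data$tech_rep)
    ) |>
    dplyr::select("well_id", "focal", "partner", "scenario", "env",
                  "bio_rep", "tech_rep")
}

# Effective growth rate of a lineage in a well: the scenario multiplier
# applies only when a non-self partner supplies the cue.
effective_mu <- function(wells, lineages) {
  prof <- lineages[match(wells$focal, lineages$lineage_id), ]
  mult <- rep(1, nrow(wells))
  for (sc in PAIRED_SCENARIOS) {
    sel <- wells$scenario == sc & !is.na(wells$partner) &
      wells$partner != wells$focal
    mult[sel] <- prof[[paste0("react_", sc)]][sel]
  }
  prof$mu_mono * mult
}

#' Simulate a full experiment
#'
#' Generates daily cell-count series and per-well photophysiology records for
#' every well of a design. Densities follow noiseless exponential growth
#' `N * exp(mu_eff * t)` from the inoculum, multiplied by lognormal noise:
#' a biological-replicate deviate on the growth rate shared by all wells of
#' the same lineage and replicate population, and independent per-observation
#' noise on each count. Direct co-culture wells carry two interleaved series,
#' the focal lineage and its GFP-tagged partner. Self-pairs and monocultures
#' grow at the intrinsic rate (reactiveness 1).
#'
#' @param design An [experiment_design()].
#' @param pq Photosynthetic quotient (mol O2 per mol C) used to express the
#'   generated per-cell oxygen rates; the analysis layer converts back with
#'   its own `pq` so round trips are exact when the two agree.
#' @param resp_fraction Fraction of gross photosynthesis lost to respiration
#'   when generating `gp_o2` from `np_o2`.
#' @return An object of class `pico_experiment`: a list with `counts`
#'   (tibble: well_id, focal, partner, scenario, env, bio_rep, tech_rep,
#'   series, transfer, day, density), `photo` (tibble: well_id plus per-cell
#'   oxygen rates and carbon quota) and the `design` itself.
#' @export
simulate_experiment <- function(design, pq = 1.4, resp_fraction = 0.3) {
  stopifnot(inherits(design, "experiment_design"))
  lineages <- design$lineages
  withr::with_seed(design$seed, {
    wells <- design_wells(design)
    wells$series <- "focal"

    # A direct co-culture well also tracks its GFP-tagged partner population,
    # growing at the partner's intrinsic rate modulated by the focal cue.
    direct <- wells[wells$scenario == "direct", ]
    if (nrow(direct) > 0) {
      gfp <- direct
      gfp$series <- "gfp_partner"
      tmp <- gfp$focal; gfp$focal <- gfp$partner; gfp$partner <- tmp
      wells <- dplyr::bind_rows(wells, gfp)
    }

    mu_eff <- effective_mu(wells, lineages)
    if (any(mu_eff > design$mu_ceiling))
      stop(sprintf(
        "design implies effective growth up to %.2f day^-1, above the plausibility ceiling of %s day^-1",
        max(mu_eff), format(design$mu_ceiling)), call. = FALSE)

    prof <- lineages[match(wells$focal, lineages$lineage_id), ]

    # One growth-rate deviate per lineage x biological replicate population,
    # shared across that population's wells; lognormal with meanlog 0.
    bio_key <- paste(wells$focal, wells$bio_rep, sep = "|")
    keys <- unique(bio_key)
    cv_by_key <- prof$cv_bio[match(keys, bio_key)]
    bio_dev <- setNames(rnorm(length(keys), 0, cv_by_key), keys)
    mu_well <- mu_eff * exp(unname(bio_dev[bio_key]))

    # Expand to daily observations, restarting from the inoculum after each
    # transfer. The pre-transfer count on a boundary day closes one segment
    # and the next segment reopens at the inoculum on the same absolute day,
    # so segments are distinguished by the `transfer` index.
    bounds <- c(0, design$transfer_days, design$duration_days)
    seg <- dplyr::bind_rows(lapply(seq_len(length(bounds) - 1L), function(k) {
      tibble::tibble(transfer = k,
                     day = seq(bounds[k], bounds[k + 1L]),
                     t_rel = .data$day - bounds[k])
    }))
    counts <- tidyr::expand_grid(
      dplyr::mutate(wells, mu_well = mu_well,
                    cv_tech = prof$cv_tech, .row = dplyr::row_number()),
      seg
    )
    noise <- exp(rnorm(nrow(counts), 0, counts$cv_tech))
    counts$density <- design$inoculum * exp(counts$mu_well * counts$t_rel) * noise
    counts <- counts |>
      dplyr::select("well_id", "focal", "partner", "scenario", "env",
                    "bio_rep", "tech_rep", "series", "transfer", "day",
                    "density")

    # Per-well photophysiology: biomass-specific NP with its own shared
    # biological deviate, expressed as per-cell oxygen evolution.
    wl <- wells[wells$series == "focal", ]
    wprof <- lineages[match(wl$focal, lineages$lineage_id), ]
    np_key <- paste(wl$focal, wl$bio_rep, sep = "|")
    nkeys <- unique(np_key)
    np_bio <- setNames(rnorm(length(nkeys), 0,
                             wprof$cv_bio[match(nkeys, np_key)]), nkeys)
    np_spec <- wprof$np_specific * exp(unname(np_bio[np_key])) *
      exp(rnorm(nrow(wl), 0, wprof$cv_tech))
    np_o2 <- np_spec * wprof$carbon_quota * pq / 12.011
    photo <- tibble::tibble(
      well_id = wl$well_id, focal = wl$focal, partner = wl$partner,
      scenario = wl$scenario, env = wl$env,
      bio_rep = wl$bio_rep, tech_rep = wl$tech_rep,
      np_o2 = np_o2, gp_o2 = np_o2 / (1 - resp_fraction),
      carbon_quota = wprof$carbon_quota
    )

    structure(list(counts = counts, photo = photo, design = design),
              class = "pico_experiment")
  })
}

#' @export
print.pico_experiment <- function(x, ...) {
  cat("Simulated experiment:", dplyr::n_distinct(x$counts$well_id), "wells,",
      nrow(x$counts), "count observations,", nrow(x$photo),
      "photophysiology records\n")
  invisible(x)
}

#' Simulate a flow-cytometry-like event table
#'
#' Draws single-event scatter/fluorescence records for one well: intact cells
#' sit above the size (fsc) and chlorophyll (fl3) gate centres, debris falls
#' below the chlorophyll gate, and GFP-tagged cells carry an elevated green
#' channel. The hidden `event_class` column records the ground truth for
#' testing only; the gating pipeline never reads it.
#'
#' @param density Cell density of the well (cells ml^-1).
#' @param debris_fraction,gfp_fraction Per-event probabilities of an event
#'   being debris, and of a cell being GFP-tagged; both in `[0, 1)`.
#' @param gates A [gate_config()] supplying the sampled volume.
#' @param n_events Total events to draw; defaults to
#'   `density * sample_volume / (1 - debris_fraction)` so the expected number
#'   of true cells matches the well density times the sampled volume.
#' @param channels List of `c(center, sdlog)` pairs for the lognormal channel
#'   distributions of each subpopulation.
#' @param well_id Label copied into the table.
#' @return Tibble with columns `well_id`, `fsc`, `fl3`, `green`,
#'   `event_class`.
#' @export
simulate_events <- function(density, debris_fraction = 0, gfp_fraction = 0,
                            gates = gate_config(), n_events = NULL,
                            channels = list(
                              cell_fsc = c(200, 0.25), cell_fl3 = c(300, 0.25),
                              debris_fsc = c(30, 0.40), debris_fl3 = c(5, 0.50),
                              wt_green = c(5, 0.40), gfp_green = c(500, 0.30)
                            ),
                            well_id = "well") {
  if (debris_fraction < 0 || debris_fraction >= 1)
    abort_domain("debris_fraction", "must lie in [0, 1)")
  if (gfp_fraction < 0 || gfp_fraction >= 1)
    abort_domain("gfp_fraction", "must lie in [0, 1)")
  n_events <- n_events %||%
    max(1L, round(density * gates$sample_volume / (1 - debris_fraction)))
  is_debris <- runif(n_events) < debris_fraction
  is_gfp <- !is_debris & runif(n_events) < gfp_fraction
  cls <- ifelse(is_debris, "debris", ifelse(is_gfp, "gfp_cell", "cell"))
  draw <- function(par, n) rlnorm(n, log(par[1]), par[2])
  n <- n_events
  fsc <- ifelse(is_debris, draw(channels$debris_fsc, n), draw(channels$cell_fsc, n))
  fl3 <- ifelse(is_debris, draw(channels$debris_fl3, n), draw(channels$cell_fl3, n))
  green <- ifelse(is_gfp, draw(channels$gfp_green, n), draw(channels$wt_green, n))
  tibble::tibble(well_id = well_id, fsc = fsc, fl3 = fl3, green = green,
                 event_class = cls)
}
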