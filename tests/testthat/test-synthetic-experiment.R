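test_that("noise-free wells follow closed-form exponential growth", {
  # one lineage at mu = ln(1000)/7 starting from 100 cells/ml reaches 1e5
  mu <- log(1000) / 7
  panel <- make_panel(mu = mu)
  design <- make_design(panel, scenarios = "monoculture", n_bio = 1,
                        n_tech = 1, duration_days = 7)
  sim <- simulate_experiment(design)
  well <- sim$counts[sim$counts$focal == "L01", ]
  expect_equal(well$density, 100 * exp(mu * well$day), tolerance = 1e-12)
  expect_equal(well$density[well$day == 0], 100)
  expect_equal(well$density[well$day == 7], 1e5, tolerance = 1e-9)
})

test_that("unit reactiveness makes every treatment identical to monoculture", {
  panel <- make_panel(mu = c(0.5, 0.9))
  design <- make_design(panel, n_bio = 1, n_tech = 1)
  sim <- simulate_experiment(design)
  g <- estimate_growth(sim$counts)
  g <- g[g$series == "focal", ]
  for (lin in c("L01", "L02")) {
    mus <- g$mu[g$focal == lin]
    expect_equal(mus, rep(mus[1], length(mus)), tolerance = 1e-12)
  }
})

test_that("full-factorial well counts match explicit enumeration", {
  panel <- make_panel(mu = seq(0.5, 1.0, length.out = 6))
  design <- make_design(panel, n_bio = 3, n_tech = 3)
  wells <- simulate_experiment(design)$counts |>
    dplyr::distinct(well_id, scenario, series)
  n_by <- table(wells$scenario[wells$series == "focal"])
  expect_equal(unname(n_by[["monoculture"]]), 6 * 9)
  for (sc in c("thincert", "spike", "direct"))
    expect_equal(unname(n_by[[sc]]), 6 * 6 * 9)
  # direct wells carry the interleaved GFP partner series, others do not
  expect_equal(sum(wells$series == "gfp_partner"), 6 * 6 * 9)
  expect_true(all(wells$scenario[wells$series == "gfp_partner"] == "direct"))
})

test_that("self-pairs are unmodulated controls while non-self pairs react", {
  react <- function(mu) c(thincert = 1.5, spike = 1.2, direct = 2)
  panel <- make_panel(mu = c(0.4, 0.6), reactiveness = react)
  design <- make_design(panel, n_bio = 1, n_tech = 1)
  g <- estimate_growth(simulate_experiment(design)$counts)
  g <- g[g$series == "focal", ]
  self <- g[!is.na(g$partner) & g$partner == g$focal & g$scenario == "thincert", ]
  mono <- g[g$scenario == "monoculture", ]
  expect_equal(sort(self$mu), sort(mono$mu), tolerance = 1e-12)
  cross <- g[!is.na(g$partner) & g$partner != g$focal, ]
  mult <- c(thincert = 1.5, spike = 1.2, direct = 2)
  base <- setNames(c(0.4, 0.6), c("L01", "L02"))
  expect_equal(cross$mu, unname(base[cross$focal] * mult[cross$scenario]),
               tolerance = 1e-12)
})

test_that("lognormal noise is log-unbiased and bio deviates are shared", {
  panel <- make_panel(mu = 0.7, cv_bio = 0.1, cv_tech = 0.08)
  design <- make_design(panel, scenarios = "monoculture", n_bio = 40,
                        n_tech = 4, duration_days = 5, seed = 9)
  sim <- simulate_experiment(design)
  counts <- sim$counts
  # log-residuals around each well's own exponential trend average to zero
  g <- estimate_growth(counts)
  resid <- counts |>
    dplyr::inner_join(g[, c("well_id", "mu")], by = "well_id") |>
    dplyr::mutate(r = log(density) - log(100) - mu * day)
  expect_lt(abs(mean(resid$r)), 0.01)
  # wells of the same biological replicate share one growth-rate deviate:
  # between-bio-rep spread of mu dominates between-tech spread
  per_well <- g |>
    dplyr::group_by(bio_rep) |>
    dplyr::summarise(m = mean(mu), s = sd(mu))
  expect_gt(sd(per_well$m), 2 * mean(per_well$s))
})

test_that("generator output is reproducible byte-for-byte given a seed", {
  panel <- make_panel(mu = c(0.5, 0.8), cv_bio = 0.1, cv_tech = 0.05)
  design <- make_design(panel, n_bio = 2, n_tech = 2, seed = 123)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_pipeline_csv(simulate_experiment(design)$counts, f1, list(seed = 123))
  write_pipeline_csv(simulate_experiment(design)$counts, f2, list(seed = 123))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("implausibly fast designs and bad scenarios are rejected", {
  fast <- make_panel(mu = c(2, 1.8), reactiveness = function(mu)
    c(thincert = 2, spike = 1, direct = 1))
  design <- make_design(fast, n_bio = 1, n_tech = 1)
  expect_error(simulate_experiment(design), "plausibility ceiling")
  expect_error(experiment_design(make_panel(), scenarios = "chemostat"))
  expect_error(experiment_design(make_panel(), duration_days = 0), "duration")
  expect_error(lineage_profile("x", mu_mono = -1), "mu_mono")
  expect_error(lineage_profile("x", mu_mono = 0.5,
                               reactiveness = c(thincert = -1, spike = 1,
                                                direct = 1)),
               "reactiveness")
})

test_that("paper-like panels stay inside the plausible growth range", {
  withr::with_seed(21, {
    for (env in c("ambient", "elevated")) {
      panel <- paper_like_lineages(20, env = env)
      expect_true(all(panel$mu_mono >= 0.45 & panel$mu_mono <= 1.1))
    }
  })
})

test_that("elevated panels respond more weakly than ambient ones on average", {
  # the damping calibration targets the panel-level expectation, so check it
  # at a panel size where sampling noise is negligible
  withr::with_seed(35, {
    mean_mag <- function(env) {
      p <- paper_like_lineages(4000, env = env)
      mean(abs(log(c(p$react_thincert, p$react_spike, p$react_direct))))
    }
    fold <- mean_mag("ambient") / mean_mag("elevated")
    expect_gt(fold, 1.1)
    expect_lt(fold, 1.5)
  })
})

test_that("transfers reset densities to the inoculum and segments re-grow", {
  panel <- make_panel(mu = 0.8)
  design <- make_design(panel, scenarios = "monoculture", n_bio = 1,
                        n_tech = 1, duration_days = 14, transfer_days = 7)
  counts <- simulate_experiment(design)$counts
  one <- counts[counts$focal == "L01", ]
  expect_equal(sort(unique(one$transfer)), c(1, 2))
  seg2 <- one[one$transfer == 2, ]
  expect_equal(seg2$density[seg2$day == 7], 100)  # restarts at the inoculum
  expect_equal(seg2$density, 100 * exp(0.8 * (seg2$day - 7)), tolerance = 1e-12)
})

test_that("event tables honour debris and GFP fractions with hidden truth", {
  ev0 <- withr::with_seed(5, simulate_events(2000, debris_fraction = 0))
  expect_true(all(ev0$event_class %in% c("cell", "gfp_cell")))

  ev <- withr::with_seed(5, simulate_events(1e5, debris_fraction = 0.2,
                                            gfp_fraction = 0.5,
                                            n_events = 1000))
  expect_equal(nrow(ev), 1000)
  gates <- gate_config()
  # the binomially drawn debris events are the ones below the fl3 gate
  n_debris <- sum(ev$event_class == "debris")
  expect_equal(sum(ev$fl3 < gates$fl3_min), n_debris)
  # green channel is bimodal: the two hidden subpopulations straddle the gate
  wt <- ev$green[ev$event_class == "cell"]
  gfp <- ev$green[ev$event_class == "gfp_cell"]
  expect_lt(stats::quantile(wt, 0.99), gates$green_min)
  expect_gt(stats::quantile(gfp, 0.01), gates$green_min)
  expect_error(simulate_events(1000, debris_fraction = 1), "debris_fraction")
})
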