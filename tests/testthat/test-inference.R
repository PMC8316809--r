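test_that("AICc matches its algebraic definition", {
  expect_equal(aicc(-10, 3, 20), 27.5) # 26 + 24/16
  expect_equal(aicc(-10, 0, 20), -2 * -10) # no parameters: AICc = AIC
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 6, tolerance = 1e-6) # n -> Inf
  expect_error(aicc(-10, 5, 6), "n <= k")
  withr::with_seed(2, {
    for (i in 1:20) {
      ll <- runif(1, -100, 0); k <- sample(1:6, 1); n <- k + 1 + sample(1:50, 1)
      expect_equal(aicc(ll, k, n),
                   (-2 * ll + 2 * k) + 2 * k * (k + 1) / (n - k - 1))
    }
  })
})

test_that("mixed-model fits recover planted coefficients", {
  withr::with_seed(8, {
    # continuous slope, no random variance
    d <- tibble::tibble(x = runif(500), focal = "L1", bio_rep = 1)
    d$y <- 0.2 + 0.5 * d$x + rnorm(500, 0, 0.1)
    fit <- fit_growth_model(d, "y", fixed_terms = "x", random_grouping = "none")
    sl <- fit$coefficients[fit$coefficients$term == "x", ]
    expect_lt(abs(sl$estimate - 0.5), 2 * sl$se)

    # balanced two-group difference with random bio-rep structure
    d2 <- sim_lineage_data(2, 10, 3, lineage_sd = 0, bio_sd = 0.03,
                           res_sd = 0.03)
    d2$mu <- d2$mu + ifelse(d2$focal == "L02", 0.25, 0)
    fit2 <- fit_growth_model(d2, "mu", fixed_terms = "focal")
    co <- fit2$coefficients
    est <- co$estimate[co$term == "focalL02"]
    expect_lt(abs(est - 0.25), 3 * co$se[co$term == "focalL02"])
    expect_true(fit2$converged)
  })
})

test_that("constant outcomes fit without blowing up", {
  d <- tibble::tibble(focal = rep(c("a", "b"), 10), bio_rep = 1,
                      x = runif(20), y = 1)
  fit <- fit_growth_model(d, "y", fixed_terms = "x", random_grouping = "none")
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-9)
  expect_true(is.finite(fit$loglik))
})

test_that("singular random-effect variance is reported, not hidden", {
  # bio-rep group means are exactly equal within each lineage, so the
  # random-intercept variance is estimated at its boundary (zero)
  d <- tidyr::expand_grid(focal = sprintf("L%02d", 1:4), bio_rep = 1:3,
                          tech = 1:3)
  lin_eff <- setNames(c(0, 0.1, 0.2, 0.3), sprintf("L%02d", 1:4))
  d$mu <- 0.7 + lin_eff[d$focal] + rep(c(-0.05, 0, 0.05), nrow(d) / 3)
  fit <- fit_growth_model(d, "mu", fixed_terms = "focal")
  expect_true(fit$singular)
  expect_true(fit$converged)
})

test_that("likelihood-ratio test has the stated mechanics and guards", {
  withr::with_seed(12, {
    d <- sim_lineage_data(5, 3, 3, lineage_sd = 0.1, bio_sd = 0.04,
                          res_sd = 0.03)
    full <- fit_growth_model(d, "mu", fixed_terms = "focal")
    red <- fit_growth_model(d, "mu", fixed_terms = character())
    t <- lrt_fixed_effect(full, red)
    expect_equal(t$chi2, 2 * (full$loglik - red$loglik))
    expect_equal(t$delta_df, 4)
    expect_equal(t$p, pchisq(t$chi2, 4, lower.tail = FALSE))

    # identical models: chi2 0, p 1
    t0 <- lrt_fixed_effect(full, full)
    expect_equal(t0$chi2, 0)
    expect_equal(t0$p, 1)

    # REML and non-converged fits are refused; so are non-nested specs
    full_reml <- fit_growth_model(d, "mu", fixed_terms = "focal", reml = TRUE)
    expect_error(lrt_fixed_effect(full_reml, red), "maximum-likelihood")
    broken <- red; broken$converged <- FALSE
    expect_error(lrt_fixed_effect(full, broken), "non-converged")
    other <- fit_growth_model(dplyr::mutate(d, z = runif(dplyr::n())),
                              "mu", fixed_terms = "z")
    expect_error(lrt_fixed_effect(full, other), "not nested")
  })
})

test_that("the LRT statistic is invariant to affine rescaling of the outcome", {
  withr::with_seed(14, {
    d <- sim_lineage_data(4, 3, 3, lineage_sd = 0.08, bio_sd = 0.03,
                          res_sd = 0.03)
    d$mu2 <- 5 * d$mu - 2
    chi <- function(out) {
      f <- fit_growth_model(d, out, fixed_terms = "focal")
      r <- fit_growth_model(d, out, fixed_terms = character())
      lrt_fixed_effect(f, r)$chi2
    }
    expect_equal(chi("mu"), chi("mu2"), tolerance = 1e-4)
  })
})

test_that("a planted lineage effect at the experiment's scale is detected", {
  withr::with_seed(16, {
    d <- sim_lineage_data(6, 3, 3, lineage_sd = 0.08, bio_sd = 0.05,
                          res_sd = 0.05)
    full <- fit_growth_model(d, "mu", fixed_terms = "focal")
    red <- fit_growth_model(d, "mu", fixed_terms = character())
    expect_equal(lrt_fixed_effect(full, red)$delta_df, 5)
  })
})

test_that("reactiveness model recovers an exact linear relationship", {
  # response is an exact linear function of surplus, noise off
  grid <- tidyr::expand_grid(focal = sprintf("L%d", 1:6), bio_rep = 1:3,
                             partner = "P", scenario = "spike",
                             env = "ambient")
  surplus <- setNames(seq(10, 110, length.out = 6), sprintf("L%d", 1:6))
  budgets <- tibble::tibble(
    well_id = paste0("w", seq_len(18)),
    focal = rep(sprintf("L%d", 1:6), each = 3), env = "ambient",
    bio_rep = rep(1:3, 6)
  )
  budgets$surplus_pct <- unname(surplus[budgets$focal])
  budgets$np_growth_ratio <- 1 + budgets$surplus_pct / 100
  budgets$reason <- ""
  responses <- grid
  responses$response <- 0.8 + 0.004 * surplus[responses$focal]
  fit <- fit_reactiveness_model(responses, budgets,
                                random_grouping = "none")
  expect_equal(fit$results$slope, 0.004, tolerance = 1e-6)
  expect_equal(fit$results$best_model, "with_predictor")
})

test_that("scenarios with too few lineages are skipped with a message", {
  responses <- tibble::tibble(focal = c("A", "B"), partner = "C",
                              scenario = "spike", env = "ambient",
                              bio_rep = 1, response = c(1, 1.2))
  budgets <- tibble::tibble(well_id = c("w1", "w2"), focal = c("A", "B"),
                            env = "ambient", bio_rep = 1,
                            surplus_pct = c(20, 60), reason = "")
  expect_message(fit <- fit_reactiveness_model(responses, budgets,
                                               random_grouping = "none"),
                 "skipping")
  expect_equal(nrow(fit$results), 0)
})
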