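# Small deterministic panels and designs used across tests.

# A noise-free panel with fixed growth rates and unit reactiveness unless
# overridden; useful wherever closed-form expectations are asserted.
make_panel <- function(mu = c(0.5, 0.7, 0.9), env = "ambient",
                       reactiveness = NULL, cv_bio = 0, cv_tech = 0,
                       np_specific = NULL) {
  dplyr::bind_rows(lapply(seq_along(mu), function(i) {
    react <- if (is.null(reactiveness)) c(thincert = 1, spike = 1, direct = 1)
             else reactiveness(mu[i])
    lineage_profile(sprintf("L%02d", i), env = env, mu_mono = mu[i],
                    reactiveness = react,
                    np_specific = if (is.null(np_specific)) 1.92 * mu[i] / 24
                                  else np_specific,
                    cv_bio = cv_bio, cv_tech = cv_tech)
  }))
}

make_design <- function(panel = make_panel(), scenarios = SCENARIOS(),
                        n_bio = 2, n_tech = 2, duration_days = 7, seed = 42,
                        ...) {
  experiment_design(panel, scenarios = scenarios, n_bio = n_bio,
                    n_tech = n_tech, duration_days = duration_days,
                    seed = seed, ...)
}

SCENARIOS <- function() c("monoculture", "thincert", "spike", "direct")

# Hierarchical growth data with planted lineage, biological-replicate and
# residual components; the workhorse for the mixed-model operating
# characteristics.
sim_lineage_data <- function(n_lin, n_bio, n_tech, lineage_sd, bio_sd, res_sd,
                             grand = 0.7) {
  d <- tidyr::expand_grid(focal = sprintf("L%02d", seq_len(n_lin)),
                          bio_rep = seq_len(n_bio), tech = seq_len(n_tech))
  lin_eff <- setNames(rnorm(n_lin, 0, lineage_sd), unique(d$focal))
  bio_eff <- rnorm(n_lin * n_bio, 0, bio_sd)
  names(bio_eff) <- unique(paste(d$focal, d$bio_rep))
  d$mu <- grand + lin_eff[d$focal] + bio_eff[paste(d$focal, d$bio_rep)] +
    rnorm(nrow(d), 0, res_sd)
  d
}

# Growth table for a planted within/between variance structure: one row per
# biological replicate, mu = lineage mean + N(0, sd_within).
planted_growth_table <- function(n_lineages, n_reps, sd_between, sd_within,
                                 env, mean_mu = 0.775) {
  lin_means <- rnorm(n_lineages, mean_mu, sd_between)
  tibble::tibble(
    focal = rep(sprintf("L%03d", seq_len(n_lineages)), each = n_reps),
    env = env,
    bio_rep = rep(seq_len(n_reps), times = n_lineages),
    mu = rep(lin_means, each = n_reps) + rnorm(n_lineages * n_reps, 0, sd_within)
  )
}
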