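# Shared fixtures: all synthetic, built in code at test time.

panel8 <- default_cytotypes()

# genome sizes drawn straight from the 8-group panel (no FCM noise)
sim_panel_gs <- function(n, seed, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / 8, 8)
  set.seed(seed)
  g <- sample(8, n, replace = TRUE, prob = weights)
  list(gs = stats::rnorm(n, panel8$gs_mean[g], panel8$gs_sd[g]),
       group = panel8$label[g])
}

# a small, fast scenario for pipeline-level tests: equal prevalences keep
# every group populated at modest sample sizes
small_scenario <- function(n_populations = 40, n_particles = 1200,
                           seed = 11, ...) {
  ct <- panel8
  ct$prevalence <- rep(1 / 8, 8)
  scenario_config(cytotypes = ct, n_populations = n_populations,
                  n_particles = n_particles, seed = seed, ...)
}

# hand-built mixture object for tests that need exact parameters
manual_gmm <- function(means, sds, weights) fc_gmm_model(means, sds, weights)
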