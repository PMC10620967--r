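make_assignments <- function(...) {
  # lists of per-population group labels -> assignments data.frame
  pops <- list(...)
  do.call(rbind, lapply(seq_along(pops), function(i) data.frame(
    sample_id = paste0("p", i, "_", seq_along(pops[[i]])),
    population_id = names(pops)[i],
    group = pops[[i]], stringsAsFactors = FALSE)))
}

test_that("population summaries distinguish pure from mixed", {
  asg <- make_assignments(
    A = rep("6xC", 15),
    B = c(rep("4xA", 10), rep("5x", 2), rep("6xC", 3)),
    C = c(rep("2x", 12), rep("UNASSIGNED", 3)))
  pops <- data.frame(population_id = c("A", "B", "C"),
                     habitat = c("anthropogenic", "natural", "natural"))
  ps <- summarize_populations(asg, pops)
  s <- ps$summaries
  expect_equal(s$is_mixed, c(FALSE, TRUE, FALSE))
  expect_equal(s$n_groups, c(1, 3, 1))
  expect_equal(s$combination[2], "4xA+5x+6xC")
  # unassigned individuals excluded from groups but reported
  expect_equal(s$n_unassigned, c(0, 0, 3))
  expect_equal(s$n_assigned, c(15, 15, 12))
  # counts conserve assigned individuals
  expect_equal(sum(ps$counts$n), sum(asg$group != "UNASSIGNED"))
})

test_that("unknown populations and empty ones are handled loudly", {
  asg <- make_assignments(A = rep("6xC", 3))
  pops <- data.frame(population_id = c("A", "B"), habitat = "natural")
  ps <- summarize_populations(asg, pops)
  expect_equal(ps$summaries$n_assigned[ps$summaries$population_id == "B"], 0)
  asg_bad <- make_assignments(Z = rep("6xC", 3))
  expect_error(summarize_populations(asg_bad, pops), "unknown")
  pops_bad <- data.frame(population_id = "A", habitat = "urban")
  expect_error(summarize_populations(asg, pops_bad), "habitat")
})

test_that("recovered mixed fraction matches the generated one under truth labels", {
  cfg <- scenario_config(n_populations = 50, n_particles = 500,
                         mixed_fraction = 0.38, seed = 41)
  study <- simulate_study(cfg)
  # with error-free classification (truth labels), the recovered mixed
  # fraction equals the realised generated fraction exactly
  asg <- data.frame(sample_id = study$truth$sample_id,
                    population_id = study$truth$population_id,
                    group = study$truth$true_group)
  ps <- summarize_populations(asg, study$populations)
  realised <- vapply(split(study$truth$true_group,
                           study$truth$population_id),
                     function(g) length(unique(g)) >= 2, logical(1))
  expect_equal(mean(ps$summaries$is_mixed), mean(realised))
})

test_that("intersection counts conserve populations and order by frequency", {
  asg <- make_assignments(
    A = rep("6xC", 5), B = rep("6xC", 5), C = c("2x", "6xC"),
    D = rep("2x", 4), E = rep("6xC", 2))
  pops <- data.frame(population_id = c("A", "B", "C", "D", "E"),
                     habitat = c("anthropogenic", "natural", "natural",
                                 "natural", "anthropogenic"))
  ic <- intersection_counts(summarize_populations(asg, pops))
  expect_equal(sum(ic$n_populations), 5)
  expect_equal(ic$combination[1], "6xC")
  expect_equal(ic$n_populations[1], 3)
  expect_true(all(ic$n_natural + ic$n_anthropogenic == ic$n_populations))
  # ties broken lexicographically
  expect_equal(ic$combination[2:3], c("2x", "2x+6xC"))
  # habitat columns sum to the habitat totals
  expect_equal(sum(ic$n_anthropogenic), 2)
  expect_equal(sum(ic$n_natural), 3)
})

test_that("habitat association counts groups per habitat and is reproducible", {
  asg <- make_assignments(
    A = rep("2x", 3), B = rep("2x", 3),
    C = rep("6xC", 3), D = rep("6xC", 3), E = c("2x", "6xC"))
  pops <- data.frame(population_id = LETTERS[1:5],
                     habitat = c("natural", "natural", "anthropogenic",
                                 "anthropogenic", "natural"))
  ps <- summarize_populations(asg, pops)
  ha1 <- habitat_association(ps, n_perm = 200, seed = 5)
  ha2 <- habitat_association(ps, n_perm = 200, seed = 5)
  expect_identical(ha1, ha2)
  # 2x occurs only in natural populations here
  expect_equal(ha1$n_anthropogenic[ha1$group == "2x"], 0)
  expect_equal(ha1$n_natural[ha1$group == "2x"], 3)
  expect_true(all(ha1$p_value > 0 & ha1$p_value <= 1))
})

test_that("degenerate habitat structure skips the test with a notice", {
  asg <- make_assignments(A = rep("2x", 3), B = rep("6xC", 3))
  pops <- data.frame(population_id = c("A", "B"), habitat = "natural")
  ps <- summarize_populations(asg, pops)
  expect_message(ha <- habitat_association(ps, n_perm = 100, seed = 1),
                 "skipped")
  expect_true(all(is.na(ha$p_value)))
  # a single population is an error
  asg1 <- make_assignments(A = rep("2x", 3))
  pops1 <- data.frame(population_id = "A", habitat = "natural")
  expect_error(habitat_association(summarize_populations(asg1, pops1)),
               "at least 2")
})

test_that("permutation p-values are valid under habitat independence", {
  # habitats assigned independently of composition: the test's rejection
  # rate must not exceed its nominal level (discreteness makes it
  # conservative, never anti-conservative)
  n_rep <- 60
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n_pop <- 30
    groups <- sample(c("2x", "6xB", "6xC"), n_pop, replace = TRUE)
    asg <- data.frame(sample_id = paste0("s", seq_len(n_pop)),
                      population_id = paste0("P", seq_len(n_pop)),
                      group = groups)
    pops <- data.frame(population_id = paste0("P", seq_len(n_pop)),
                       habitat = sample(c("natural", "anthropogenic"),
                                        n_pop, replace = TRUE))
    ps <- summarize_populations(asg, pops)
    ha <- habitat_association(ps, n_perm = 400, seed = r)
    pvals[r] <- ha$p_value[ha$group == "6xC"]
  }
  # the discrete permutation distribution makes p-values super-uniform
  # (conservative), so the calibration check is one-sided type-I control
  for (alpha in c(0.05, 0.1, 0.25)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(pvals <= alpha), alpha + slack)
  }
})
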