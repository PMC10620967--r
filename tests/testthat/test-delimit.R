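test_that("ploidy follows the chromosome count, aneuploids are rejected", {
  expect_equal(ploidy_from_count(14), 2L)
  expect_equal(ploidy_from_count(49), 7L)
  expect_equal(ploidy_from_count(c(14, 28, 35, 42, 49)), c(2L, 4L, 5L, 6L, 7L))
  expect_error(ploidy_from_count(15), "aneuploid")
  expect_error(ploidy_from_count(0), "positive")
})

test_that("components are labelled by anchored ploidy with letter suffixes", {
  sim <- sim_panel_gs(1200, 31)
  f <- fit_gmm(sim$gs, 8)
  # anchors: five per group, ploidy from the generating label
  set.seed(32)
  idx <- unlist(lapply(split(seq_along(sim$group), sim$group), sample, 5))
  anchors <- data.frame(
    sample_id = paste0("a", idx), gs = sim$gs[idx],
    two_n = 7 * panel8$ploidy[match(sim$group[idx], panel8$label)])
  mp <- suppressWarnings(map_components_to_ploidy(f, anchors))
  expect_equal(mp$label,
               c("2x", "4xA", "4xB", "5x", "6xA", "6xB", "6xC", "7x"))
  expect_equal(mp$ploidy, c(2, 4, 4, 5, 6, 6, 6, 7))
  expect_true(all(mp$n_anchors >= 1))
})

test_that("a lone component with one anchor gets an unsuffixed label", {
  f <- manual_gmm(means = 5.9, sds = 0.1, weights = 1)
  anchors <- data.frame(sample_id = "a1", gs = 5.9, two_n = 28)
  mp <- map_components_to_ploidy(f, anchors)
  expect_equal(mp$label, "4x")
})

test_that("anchor inconsistencies and uncovered components are errors", {
  f <- manual_gmm(means = c(3, 8), sds = c(0.2, 0.2), weights = c(1, 1))
  tied <- data.frame(sample_id = c("a", "b", "c"),
                     gs = c(3.0, 3.1, 8.0), two_n = c(28, 42, 42))
  expect_error(map_components_to_ploidy(f, tied), "tie")
  # a clear majority resolves boundary captures, with the minority surfaced
  mostly <- data.frame(sample_id = c("a", "b", "c", "d"),
                       gs = c(3.0, 3.1, 3.2, 8.0), two_n = c(28, 28, 35, 42))
  expect_warning(mp <- map_components_to_ploidy(f, mostly), "majority")
  expect_equal(mp$ploidy, c(4L, 6L))
  expect_equal(mp$n_conflicting, c(1L, 0L))
  uncovered <- data.frame(sample_id = "a", gs = 3.0, two_n = 28)
  expect_error(map_components_to_ploidy(f, uncovered), "without any")
})

test_that("component overlap matches the closed-form percentile intervals", {
  expect_false(component_overlap(2.587, 0.036, 5.265, 0.147))
  expect_true(component_overlap(5, 1, 5, 1))
  # 99th of N(7.752, 0.101) = 7.987 > 1st of N(8.196, 0.132) = 7.889
  expect_true(component_overlap(7.752, 0.101, 8.196, 0.132))
  # and the closed form agrees with numeric quantile inversion
  for (p in c(0.01, 0.99)) {
    for (par in list(c(7.752, 0.101), c(8.196, 0.132))) {
      closed <- qnorm(p, par[1], par[2])
      numeric_inv <- uniroot(function(q) pnorm(q, par[1], par[2]) - p,
                             c(par[1] - 8 * par[2], par[1] + 8 * par[2]),
                             tol = 1e-12)$root
      expect_equal(closed, numeric_inv, tolerance = 1e-6)
    }
  }
})

test_that("non-overlapping groups keep pure percentile intervals", {
  f <- manual_gmm(means = c(2.6, 5.3), sds = c(0.04, 0.15),
                  weights = c(0.5, 0.5))
  anchors <- data.frame(sample_id = c("a", "b"), gs = c(2.6, 5.3),
                        two_n = c(14, 28))
  mp <- map_components_to_ploidy(f, anchors)
  g <- delimit_groups(f, mp, anchors)
  expect_equal(g$low_rule, c("unbounded", "percentile"))
  expect_equal(g$high_rule, c("percentile", "unbounded"))
  expect_equal(g$high[1], qnorm(0.99, 2.6, 0.04))
  expect_equal(g$low[2], qnorm(0.01, 5.3, 0.15))
  expect_equal(g$low[1], -Inf)
  expect_equal(g$high[2], Inf)
  gb <- delimit_groups(f, mp, anchors, bounded_tails = TRUE)
  expect_equal(gb$low[1], qnorm(0.01, 2.6, 0.04))
  expect_equal(gb$high[2], qnorm(0.99, 5.3, 0.15))
})

test_that("overlapping heteroploid groups are delimited by anchor extremes", {
  f <- manual_gmm(means = c(5.97, 6.45), sds = c(0.13, 0.17),
                  weights = c(0.5, 0.5))
  anchors <- data.frame(
    sample_id = c("t1", "t2", "t3", "p1", "p2", "p3"),
    gs = c(5.80, 5.97, 6.10, 6.28, 6.45, 6.60),
    two_n = c(28, 28, 28, 35, 35, 35))
  mp <- map_components_to_ploidy(f, anchors)
  g <- delimit_groups(f, mp, anchors)
  expect_equal(g$high[1], 6.10)    # largest anchored tetraploid GS, exactly
  expect_equal(g$low[2], 6.28)     # smallest anchored pentaploid GS
  expect_equal(g$high_rule[1], "anchor")
  expect_equal(g$low_rule[2], "anchor")
  # the boundary anchors themselves belong to their own groups
  asg <- assign_groups(
    data.frame(sample_id = anchors$sample_id, genome_size = anchors$gs),
    g, anchors = anchors)
  expect_equal(asg$group, c("4x", "4x", "4x", "5x", "5x", "5x"))
  expect_false(any(asg$conflict))
})

test_that("overlapping homoploid groups keep percentile edges and an ambiguity zone", {
  f <- manual_gmm(means = c(7.752, 8.196), sds = c(0.101, 0.132),
                  weights = c(0.5, 0.5))
  anchors <- data.frame(sample_id = c("a", "b"), gs = c(7.752, 8.196),
                        two_n = c(42, 42))
  mp <- map_components_to_ploidy(f, anchors)
  g <- delimit_groups(f, mp, anchors)
  expect_equal(g$label, c("6xA", "6xB"))
  expect_equal(g$high[1], qnorm(0.99, 7.752, 0.101)) # 7.987
  expect_equal(g$low[2], qnorm(0.01, 8.196, 0.132))  # 7.889
  # a value inside the shared zone is ambiguous, hence unassigned
  mid <- data.frame(sample_id = "m", genome_size = 7.93)
  asg <- assign_groups(mid, g)
  expect_equal(asg$group, "UNASSIGNED")
  expect_match(asg$rationale, "ambiguous")
})

test_that("pathological anchor placement is a loud error", {
  # middle group overlaps both neighbours and has a single anchored
  # individual: both its edges collapse onto that one genome size
  f <- manual_gmm(means = c(5.5, 5.97, 6.45), sds = c(0.25, 0.2, 0.2),
                  weights = c(1, 1, 1))
  anchors <- data.frame(sample_id = c("d", "t", "p"),
                        gs = c(5.4, 5.9, 6.4), two_n = c(14, 28, 35))
  mp <- data.frame(component = 1:3, ploidy = c(2L, 4L, 5L),
                   label = c("2x", "4x", "5x"), n_anchors = c(1L, 1L, 1L),
                   n_conflicting = 0L)
  expect_error(delimit_groups(f, mp, anchors), "empty interval")
})

test_that("assignment respects intervals, outside values stay unassigned", {
  sim <- sim_panel_gs(1200, 33)
  f <- fit_gmm(sim$gs, 8)
  set.seed(34)
  idx <- unlist(lapply(split(seq_along(sim$group), sim$group), sample, 5))
  anchors <- data.frame(
    sample_id = paste0("s", idx), gs = sim$gs[idx],
    two_n = 7 * panel8$ploidy[match(sim$group[idx], panel8$label)])
  mp <- suppressWarnings(map_components_to_ploidy(f, anchors))
  g <- delimit_groups(f, mp, anchors)
  # intervals ordered by component mean never interleave
  expect_true(all(diff(g$low) > 0))
  expect_true(all(diff(g$high) > 0))
  meas <- data.frame(sample_id = paste0("s", seq_along(sim$gs)),
                     genome_size = sim$gs)
  asg <- suppressWarnings(assign_groups(meas, g, anchors = anchors))
  expect_equal(nrow(asg), length(sim$gs))
  # every assigned sample's GS lies inside its group's interval
  assigned <- asg[asg$group != "UNASSIGNED", ]
  gi <- match(assigned$group, g$label)
  inside <- assigned$genome_size >= g$low[gi] &
    (assigned$genome_size < g$high[gi] |
       (g$high_rule[gi] == "anchor" & assigned$genome_size == g$high[gi]))
  expect_true(all(inside))
  # assigned individuals carry their generating label in the vast
  # majority; residual errors are boundary-region individuals captured by
  # a neighbouring interval
  acc_assigned <- mean(assigned$group == sim$group[match(
    assigned$sample_id, paste0("s", seq_along(sim$gs)))])
  expect_gte(acc_assigned, 0.95)
})

test_that("a genome size of 2.587 lands in the diploid group", {
  sim <- sim_panel_gs(1200, 35)
  f <- fit_gmm(sim$gs, 8)
  set.seed(36)
  idx <- unlist(lapply(split(seq_along(sim$group), sim$group), sample, 5))
  anchors <- data.frame(
    sample_id = paste0("s", idx), gs = sim$gs[idx],
    two_n = 7 * panel8$ploidy[match(sim$group[idx], panel8$label)])
  g <- delimit_groups(f, suppressWarnings(map_components_to_ploidy(f, anchors)),
                      anchors)
  asg <- assign_groups(data.frame(sample_id = "q", genome_size = 2.587), g)
  expect_equal(asg$group, "2x")
})
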