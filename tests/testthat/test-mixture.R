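test_that("a single component reduces to the sample moments", {
  set.seed(1)
  x <- rnorm(200, 5, 0.3)
  f <- fit_gmm(x, 1)
  expect_equal(f$means, mean(x), tolerance = 1e-12)
  expect_equal(f$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_equal(f$weights, 1)
  expect_equal(f$loglik, sum(dnorm(x, f$means, f$sds, log = TRUE)))
})

test_that("the EM log-likelihood trace is non-decreasing", {
  set.seed(2)
  cases <- list(
    c(rnorm(150, 0), rnorm(150, 6, 2)),
    sim_panel_gs(400, 21)$gs,
    rexp(300) # misspecified data: monotonicity must still hold
  )
  for (x in cases) {
    for (k in c(2, 3)) {
      f <- fit_gmm(x, k, seed = 3)
      expect_true(all(diff(f$loglik_trace) >= -1e-8))
    }
  }
})

test_that("a symmetric two-component mixture is recovered", {
  set.seed(4)
  x <- c(rnorm(1000, 0), rnorm(1000, 10))
  f <- fit_gmm(x, 2)
  expect_equal(f$weights, c(0.5, 0.5), tolerance = 0.06) # 0.5 +/- 0.03 each
  expect_equal(f$means, c(0, 10), tolerance = 0.12)
  expect_equal(f$sds, c(1, 1), tolerance = 0.12)
})

test_that("EM attains at least the best likelihood on a dense grid (k = 2)", {
  set.seed(5)
  x <- c(rnorm(25, 2, 0.5), rnorm(25, 6, 0.5))
  f <- fit_gmm(x, 2)
  # independent brute-force oracle: dense grid over means, SDs and weight
  grid_ll <- function(m1, m2, s1, s2, w)
    sum(log(w * dnorm(x, m1, s1) + (1 - w) * dnorm(x, m2, s2)))
  mgrid <- seq(min(x), max(x), length.out = 25)
  sgrid <- seq(0.2, 1.5, length.out = 8)
  wgrid <- seq(0.1, 0.9, by = 0.1)
  best <- -Inf
  for (m1 in mgrid) for (m2 in mgrid) if (m1 < m2)
    for (s1 in sgrid) for (s2 in sgrid) for (w in wgrid) {
      ll <- grid_ll(m1, m2, s1, s2, w)
      if (ll > best) best <- ll
    }
  expect_gte(f$loglik, best - 1e-3)
})

test_that("fitted weights and responsibilities are normalised", {
  for (s in 1:3) {
    x <- sim_panel_gs(300, s)$gs
    f <- fit_gmm(x, 4, seed = s)
    expect_lt(abs(sum(f$weights) - 1), 1e-9)
    expect_true(all(f$sds >= 1e-4))
    cl <- classify(f, x)
    expect_true(all(abs(rowSums(cl$responsibilities) - 1) < 1e-9))
    expect_true(all(cl$responsibilities >= 0 & cl$responsibilities <= 1))
  }
})

test_that("the fit is invariant to permuting the input values", {
  x <- sim_panel_gs(400, 6)$gs
  f1 <- fit_gmm(x, 3, seed = 7)
  f2 <- fit_gmm(sample(x), 3, seed = 7)
  expect_equal(f1$means, f2$means, tolerance = 1e-9)
  expect_equal(f1$sds, f2$sds, tolerance = 1e-9)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-9)
})

test_that("the fit agrees with an independent mixture implementation", {
  suppressMessages(library(mclust)) # Mclust resolves helpers via search path
  set.seed(8)
  x <- c(rnorm(300, 2, 0.4), rnorm(300, 7, 0.8))
  f <- fit_gmm(x, 2)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$means, as.numeric(ref$parameters$mean), tolerance = 1e-3)
  expect_equal(f$weights, as.numeric(ref$parameters$pro), tolerance = 1e-3)
  expect_gte(f$loglik, ref$loglik - 1e-3)
})

test_that("degenerate inputs are rejected with clear messages", {
  expect_error(fit_gmm(c(1, 2, 3), 3), "more observations")
  expect_error(fit_gmm(rep(c(1, 2), 10), 3), "distinct")
  expect_error(fit_gmm(c(1, NA, 3), 1), "NA")
})

test_that("classification labels follow the posterior with lower-mean ties", {
  f <- manual_gmm(means = c(2, 6, 10), sds = c(0.5, 0.5, 0.5),
                  weights = c(1, 1, 1))
  cl <- classify(f, c(2, 6, 10))
  expect_equal(cl$labels, c(1, 2, 3))
  # equidistant between two identical components: tie goes to lower mean
  f2 <- manual_gmm(means = c(1, 3), sds = c(0.5, 0.5), weights = c(1, 1))
  expect_equal(classify(f2, 2)$labels, 1)
})

test_that("posterior labels recover the generating group in most cases", {
  sim <- sim_panel_gs(1200, 9)
  f <- fit_gmm(sim$gs, 8)
  cl <- classify(f, sim$gs)
  # map components to the nearest generating mean
  comp_group <- panel8$label[vapply(f$means, function(m)
    which.min(abs(panel8$gs_mean - m)), integer(1))]
  acc <- mean(comp_group[cl$labels] == sim$group)
  expect_gte(acc, 0.90)
})

test_that("redundancy flags nested vestigial components only", {
  sep <- manual_gmm(means = c(2, 6, 10), sds = c(0.3, 0.3, 0.3),
                    weights = c(0.3, 0.3, 0.4))
  expect_length(redundancy_test(sep), 0)
  # tiny component nested inside a broad one
  nest <- manual_gmm(means = c(5, 5.2, 10), sds = c(1, 0.1, 0.5),
                     weights = c(0.6, 0.005, 0.395))
  expect_equal(redundancy_test(nest), 2)
  # co-located scale-split: both heavy, same centre, one nested
  split <- manual_gmm(means = c(5, 5.01, 10), sds = c(1, 0.3, 0.5),
                      weights = c(0.35, 0.25, 0.4))
  expect_equal(redundancy_test(split), 2)
  # a modest but clearly offset neighbour above the weight floor is kept
  offset <- manual_gmm(means = c(5, 7.5, 10), sds = c(1, 0.2, 0.5),
                       weights = c(0.5, 0.05, 0.45))
  expect_length(redundancy_test(offset), 0)
  # below the weight floor a component is vestigial wherever it sits
  tiny <- manual_gmm(means = c(5, 7.5, 10), sds = c(1, 0.2, 0.5),
                     weights = c(0.5, 0.005, 0.495))
  expect_equal(redundancy_test(tiny), 2)
})

test_that("model selection keeps the largest non-redundant k", {
  set.seed(10)
  x <- c(rnorm(400, 2, 0.5), rnorm(400, 8, 0.5))
  f1 <- fit_gmm(x, 1)
  f2 <- fit_gmm(x, 2)
  sel <- select_model(list(f1, f2))
  expect_equal(sel$model$k, 2)
  expect_equal(sel$report$chosen, c(FALSE, TRUE))
  expect_true(all(c("aic", "bic", "loglik") %in% names(sel$report)))
  # single candidate passes through unchanged
  only <- select_model(list(f2))
  expect_identical(only$model, f2)
  # all-redundant candidates: smallest k with a warning
  bad <- manual_gmm(means = c(5, 5.01), sds = c(1, 0.3), weights = c(1, 1))
  expect_warning(sel2 <- select_model(list(bad)), "redundant")
  expect_equal(sel2$model$k, 2)
})
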