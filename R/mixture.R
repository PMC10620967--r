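# One-dimensional Gaussian finite mixtures over genome size: EM fitting,
# posterior classification, the redundancy criterion and model selection.

#' Fit a k-component 1D Gaussian mixture by EM
#'
#' Maximum-likelihood fitting of a finite Gaussian mixture over genome sizes
#' by expectation-maximisation (the inner loop is compiled).
#'
#' The canonical fit (`n_restarts = 1`) is deterministic: component means
#' start at the k strongest modes of a narrow-bandwidth kernel density
#' estimate of the data (bandwidth `sd(values)/30`, which resolves
#' clusters at the within-group scale), each starting component taking
#' the SD and mass of the data around its mode. When the density has
#' fewer than k modes, the surplus components are seeded *co-located* on
#' existing modes — one candidate duplication site per mode, each variant
#' run for `short_iter` EM iterations with the two best continued to
#' convergence. Co-located seeding makes over-specified k behave the way
#' it does in routine mixture software — the surplus component shrinks or
#' stays nested instead of carving arbitrary splits — which is what makes
#' [redundancy_test()] informative about whether the data support k
#' components.
#'
#' With `n_restarts > 1` (thorough mode), additional starting points — a
#' k-means partition, k evenly spaced sample quantiles, then seeded draws
#' of k distinct data points — are added to the portfolio and *every*
#' start runs to full convergence, the best log-likelihood winning
#' outright. Component SDs are floored at `sd_floor`; a run that
#' collapses a component onto the floor is discarded. Components are
#' stored sorted by mean, so the fit is invariant to permutations of the
#' input.
#'
#' @param values Numeric genome sizes, pg.
#' @param k Number of components.
#' @param max_iter Iteration cap per EM run (default 1e6).
#' @param tol Convergence: absolute log-likelihood change below `tol`.
#' @param n_restarts Number of starting points; 1 (the default) is the
#'   canonical deterministic density-mode run.
#' @param seed Integer seed; only consumed by the extra starting points
#'   when `n_restarts > 1`.
#' @param sd_floor Lower bound on component SDs, pg.
#' @param short_iter EM iterations granted to each starting point before
#'   the best one is continued to convergence (when `n_restarts > 1`).
#' @return An object of class `fc_gmm`: list with `k`, `means`, `sds`,
#'   `weights`, `loglik`, `n_iter`, `converged`, `n`, `df`, `aic`, `bic`,
#'   and `loglik_trace` (per-iteration log-likelihood of the winning run).
#' @examples
#' x <- c(rnorm(100, 0), rnorm(100, 10))
#' fit_gmm(x, k = 2, seed = 1)
#' @export
fit_gmm <- function(values, k, max_iter = 1e6, tol = 1e-8,
                    n_restarts = 1, seed = NULL, sd_floor = 1e-4,
                    short_iter = 150) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  if (k < 1) stop("k must be at least 1")
  if (n <= k) stop("need more observations (", n, ") than components (", k, ")")
  if (length(unique(values)) < k)
    stop("k (", k, ") exceeds the number of distinct values (",
         length(unique(values)), ")")

  if (k == 1) {
    m <- mean(values)
    s <- max(sqrt(mean((values - m)^2)), sd_floor)
    ll <- sum(stats::dnorm(values, m, s, log = TRUE))
    return(new_fc_gmm(k, m, s, 1, ll, 1L, TRUE, n, ll))
  }

  qs <- stats::quantile(values, probs = (seq_len(k) - 0.5) / k,
                        names = FALSE, type = 7)
  pooled <- stats::sd(values) / k
  sigma0 <- rep(max(pooled, sd_floor * 10), k)
  w0 <- rep(1 / k, k)

  # per-start local scales: a component seeded on a sparse mode with the
  # pooled SD overlaps its heavy neighbours and gets dragged off it during
  # the first iterations, so each starting component takes the SD and mass
  # of the data within two bandwidths of its mode
  bw0 <- stats::sd(values) / 30
  local_start <- function(mu0) {
    s0 <- vapply(mu0, function(m) {
      nb <- values[abs(values - m) <= 2 * bw0]
      if (length(nb) >= 3) max(stats::sd(nb), sd_floor * 10) else bw0
    }, numeric(1))
    wloc <- vapply(mu0, function(m)
      sum(abs(values - m) <= 2 * bw0), numeric(1))
    wloc <- pmax(wloc, 1)
    list(mu = mu0, sigma = s0, w = wloc / sum(wloc))
  }
  starts <- lapply(kde_mode_starts(values, k), local_start)
  best <- NULL
  with_seed(seed, {
    if (n_restarts > 1) {
      km <- tryCatch(stats::kmeans(values, k, nstart = 5),
                     error = function(e) NULL)
      if (!is.null(km)) {
        s0 <- pmax(sqrt(km$withinss / pmax(km$size, 1)), sd_floor * 10)
        s0[km$size < 2] <- max(s0)
        starts <- c(starts, list(list(mu = as.numeric(km$centers),
                                      sigma = s0, w = km$size / n)))
      }
      starts <- c(starts, list(local_start(qs)))
      for (r in seq_len(max(0, n_restarts - 3)))
        starts <- c(starts, list(local_start(sort(sample(unique(values),
                                                         k)))))
    }
    if (!length(starts))
      starts <- list(list(mu = qs, sigma = sigma0, w = w0))
    # canonical mode (n_restarts == 1): short-run the duplication-site
    # variants and continue the two best — short runs under-rank starts
    # whose co-located pairs separate slowly. Thorough mode
    # (n_restarts > 1): every start runs to full convergence and the best
    # likelihood wins outright.
    thorough <- n_restarts > 1
    budget <- if (thorough || length(starts) == 1) max_iter
              else min(short_iter, max_iter)
    runs <- list()
    for (st in starts) {
      run <- .em_run_cpp(values, st$mu, st$sigma, st$w, budget, tol,
                         sd_floor)
      if (run$collapsed) next
      runs[[length(runs) + 1]] <- run
    }
    if (length(runs)) {
      lls <- vapply(runs, `[[`, numeric(1), "loglik")
      n_cont <- if (thorough) length(runs) else 2L
      for (i in utils::head(order(lls, decreasing = TRUE), n_cont)) {
        cand <- runs[[i]]
        if (!cand$converged && cand$n_iter < max_iter) {
          cont <- .em_run_cpp(values, cand$mu, cand$sigma, cand$w,
                              max_iter - cand$n_iter, tol, sd_floor)
          if (!cont$collapsed) {
            cont$n_iter <- cont$n_iter + cand$n_iter
            cont$trace <- c(cand$trace, cont$trace)
            cand <- cont
          }
        }
        if (is.null(best) || cand$loglik > best$loglik) best <- cand
      }
    }
  })
  if (is.null(best))
    stop("EM failed: every start collapsed a component below sd_floor")
  ord <- order(best$mu)
  new_fc_gmm(k, best$mu[ord], best$sigma[ord], best$w[ord], best$loglik,
             best$n_iter, best$converged, n, best$trace)
}

# Deterministic 1D starting means: local modes of a narrow-bandwidth kernel
# density estimate, picked greedily by the probability mass they carry
# (density integrated over +/- 2 bandwidths), subject to a minimum
# separation of 4 bandwidths between accepted modes and a 1% mass floor.
# Mass, not height, ranks the modes: a narrow dense cluster is tall but a
# shot-noise ripple near it carries almost no mass of its own, and ripples
# in empty gaps fall under the floor.
#
# Returns a list of candidate starting-mean vectors. With at least k modes
# there is a single start (the k strongest). With m < k modes, unresolved
# substructure must hide inside some mode's shoulder, but which one is not
# knowable from the density alone — so one variant per candidate site is
# returned, duplicating that mode with a bandwidth-scale offset; the
# short-run likelihood race then decides. Empty list when no density can
# be computed.
kde_mode_starts <- function(values, k, min_mass = 0.01, max_variants = 8L) {
  bw <- stats::sd(values) / 30
  if (!is.finite(bw) || bw <= 0) return(list())
  d <- tryCatch(stats::density(values, bw = bw, n = 1024),
                error = function(e) NULL)
  if (is.null(d)) return(list())
  y <- d$y
  n <- length(y)
  dx <- d$x[2] - d$x[1]
  is_mode <- y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-c(1, 2)]
  idx <- which(is_mode) + 1
  if (!length(idx)) return(list())
  halfwin <- max(1L, round(2 * bw / dx))
  mass <- vapply(idx, function(i)
    sum(y[max(1, i - halfwin):min(n, i + halfwin)]) * dx, numeric(1))
  keep <- mass >= min_mass
  if (!any(keep)) keep <- mass == max(mass)
  cand <- d$x[idx][keep][order(mass[keep], decreasing = TRUE)]
  modes <- numeric(0)
  for (m in cand) {
    if (length(modes) >= k) break
    if (!length(modes) || min(abs(modes - m)) >= 4 * bw)
      modes <- c(modes, m)
  }
  if (length(modes) >= k) return(list(sort(modes)))
  extra <- k - length(modes)
  n_sites <- min(length(modes), max_variants)
  lapply(seq_len(n_sites), function(site) {
    sites <- ((site - 1 + seq_len(extra) - 1) %% length(modes)) + 1
    dup <- modes[sites] + bw * 0.5 * seq_len(extra)
    sort(c(modes, dup))
  })
}

#' Construct a mixture model from known parameters
#'
#' Builds an `fc_gmm` object directly from component parameters — for
#' classifying or delimiting against a model fitted elsewhere (e.g. read
#' back from a `model.csv`), or for constructing reference models in
#' analyses. Components are sorted by mean; weights are normalised.
#'
#' @param means,sds,weights Component parameters (equal lengths, `sds > 0`).
#' @return An `fc_gmm` with `loglik`, `aic`, `bic` set to `NA`.
#' @examples
#' m <- fc_gmm_model(means = c(2.587, 5.265), sds = c(0.036, 0.147),
#'                   weights = c(0.4, 0.6))
#' classify(m, 2.6)$labels
#' @export
fc_gmm_model <- function(means, sds, weights = rep(1, length(means))) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            all(sds > 0), all(weights > 0))
  ord <- order(means)
  structure(
    list(k = length(means), means = as.numeric(means[ord]),
         sds = as.numeric(sds[ord]),
         weights = as.numeric(weights[ord] / sum(weights)),
         loglik = NA_real_, n_iter = 0L, converged = TRUE, n = 0L,
         df = 3 * length(means) - 1, aic = NA_real_, bic = NA_real_,
         loglik_trace = numeric(0)),
    class = "fc_gmm"
  )
}

new_fc_gmm <- function(k, means, sds, weights, loglik, n_iter, converged,
                       n, trace) {
  df <- 3 * k - 1
  structure(
    list(k = as.integer(k), means = as.numeric(means),
         sds = as.numeric(sds), weights = as.numeric(weights),
         loglik = loglik, n_iter = n_iter, converged = converged,
         n = as.integer(n), df = df,
         aic = -2 * loglik + 2 * df,
         bic = -2 * loglik + log(n) * df,
         loglik_trace = trace),
    class = "fc_gmm"
  )
}

#' @export
print.fc_gmm <- function(x, digits = 4, ...) {
  cat("<fc_gmm> k = ", x$k, ", n = ", x$n,
      ", logLik = ", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(data.frame(component = seq_len(x$k),
                   mean = round(x$means, digits),
                   sd = round(x$sds, digits),
                   weight = round(x$weights, digits)), row.names = FALSE)
  invisible(x)
}

#' Posterior classification under a fitted mixture
#'
#' Computes per-observation posterior component membership probabilities
#' (responsibilities) and max-posterior labels. Posterior ties are broken
#' toward the lower-mean component, so labelling is deterministic.
#'
#' @param model A fitted `fc_gmm`.
#' @param values Numeric genome sizes.
#' @return List with `responsibilities` (n x k matrix, rows summing to 1)
#'   and `labels` (component indices, 1 = lowest mean).
#' @export
classify <- function(model, values) {
  stopifnot(inherits(model, "fc_gmm"))
  x <- as.numeric(values)
  n <- length(x)
  logd <- vapply(seq_len(model$k), function(j)
    log(model$weights[j]) +
      stats::dnorm(x, model$means[j], model$sds[j], log = TRUE),
    numeric(n))
  if (n == 1) logd <- matrix(logd, nrow = 1)
  mx <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
  resp <- exp(logd - (mx + log(rowSums(exp(logd - mx)))))
  # components are sorted by mean, so "first" maximum = lower-mean tie-break
  labels <- max.col(resp, ties.method = "first")
  list(responsibilities = resp, labels = labels)
}

#' Flag redundant mixture components
#'
#' A component is flagged as redundant when it cannot stand as a
#' genome-size group of its own, in any of three ways:
#'
#' * *Vestigiality*: its weight is below `w_min`. A fitted group carrying
#'   under ~2% of the sample is a handful of individuals — typically a
#'   clump of strays in a gap or tail — not an interpretable cytotype
#'   group.
#' * *Containment*: its central percentile interval (by default 1st to
#'   99th) lies wholly inside another component's interval, and its mean
#'   sits closer to the containing component's mean than that component's
#'   SD (a duplicated-centre fit, e.g. an EM scale-split of one group
#'   into two co-located Gaussians).
#' * *Indistinguishability*: its density overlaps another component's
#'   beyond `bc_max` on the Bhattacharyya coefficient scale (1 =
#'   identical, 0 = disjoint). Two fitted groups that overlap this much
#'   cannot be delimited as distinct genome-size groups; the
#'   lower-weight member of the pair is flagged. The default 0.4 sits
#'   well above the most overlapping pair of genuinely distinct
#'   genome-size groups seen in practice (homoploid neighbours reach
#'   roughly 0.3) and well below the near-total overlap of split fits.
#'
#' Overlap alone at the level of ordinary neighbouring cytotypes is not
#' redundancy: a genuinely distinct small group whose centre sits apart
#' from its neighbour is kept.
#'
#' @param model A fitted `fc_gmm`.
#' @param w_min Weight threshold under which a component is vestigial.
#' @param containment Two percentiles defining the component interval.
#' @param bc_max Bhattacharyya coefficient above which a pair of
#'   components is considered indistinguishable.
#' @param clauses Which of the three clauses to apply. The default applies
#'   all; structural checks (pruning a fit that duplicates structure)
#'   may drop `"vestigial"`, since a small component can be a genuine
#'   rare group.
#' @return Integer vector of redundant component indices (possibly empty).
#' @export
redundancy_test <- function(model, w_min = 0.02, containment = c(0.01, 0.99),
                            bc_max = 0.4,
                            clauses = c("vestigial", "contained", "overlap")) {
  stopifnot(inherits(model, "fc_gmm"))
  lo <- stats::qnorm(containment[1], model$means, model$sds)
  hi <- stats::qnorm(containment[2], model$means, model$sds)
  redundant <- integer(0)
  for (j in seq_len(model$k)) {
    if ("vestigial" %in% clauses && model$weights[j] < w_min) {
      redundant <- c(redundant, j)
      next
    }
    others <- setdiff(seq_len(model$k), j)
    inside <- others[lo[others] <= lo[j] & hi[j] <= hi[others]]
    if ("contained" %in% clauses && length(inside)) {
      colocated <- any(abs(model$means[j] - model$means[inside]) <
                         model$sds[inside])
      if (colocated) {
        redundant <- c(redundant, j)
        next
      }
    }
    heavier <- others[model$weights[others] >= model$weights[j]]
    if ("overlap" %in% clauses && length(heavier)) {
      bc <- bhattacharyya_normal(model$means[j], model$sds[j],
                                 model$means[heavier], model$sds[heavier])
      if (any(bc > bc_max)) redundant <- c(redundant, j)
    }
  }
  redundant
}

# Bhattacharyya coefficient between N(m1, s1) and N(m2, s2), vectorised
# over the second argument pair.
bhattacharyya_normal <- function(m1, s1, m2, s2) {
  ssum <- s1^2 + s2^2
  sqrt(2 * s1 * s2 / ssum) * exp(-(m1 - m2)^2 / (4 * ssum))
}

#' Choose among candidate mixture fits by the redundancy criterion
#'
#' Prefers the most detailed interpretable model: the largest k whose fit
#' contains no redundant component (see [redundancy_test()]). When every
#' candidate has redundant components, the smallest k is returned with a
#' warning. AIC and BIC per candidate are reported as diagnostics only; the
#' decision rests on redundancy, not on information criteria.
#'
#' @param candidates List of fitted `fc_gmm` objects.
#' @param w_min,containment Passed to [redundancy_test()].
#' @return List with `model` (the chosen fit) and `report` (data.frame with
#'   `k`, `loglik`, `aic`, `bic`, `n_redundant`, `chosen`).
#' @export
select_model <- function(candidates, w_min = 0.02,
                         containment = c(0.01, 0.99)) {
  if (inherits(candidates, "fc_gmm")) candidates <- list(candidates)
  if (!length(candidates)) stop("need at least one candidate model")
  stopifnot(all(vapply(candidates, inherits, logical(1), "fc_gmm")))
  ks <- vapply(candidates, `[[`, integer(1), "k")
  nred <- vapply(candidates, function(m)
    length(redundancy_test(m, w_min, containment)), integer(1))
  report <- data.frame(
    k = ks,
    loglik = vapply(candidates, `[[`, numeric(1), "loglik"),
    aic = vapply(candidates, `[[`, numeric(1), "aic"),
    bic = vapply(candidates, `[[`, numeric(1), "bic"),
    n_redundant = nred
  )
  clean <- which(nred == 0)
  if (length(clean)) {
    pick <- clean[which.max(ks[clean])]
  } else {
    warning("every candidate k has redundant components; ",
            "returning the smallest k", call. = FALSE)
    pick <- which.min(ks)
  }
  report$chosen <- seq_along(candidates) == pick
  list(model = candidates[[pick]], report = report)
}
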