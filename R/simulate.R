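# Synthetic FCM study generator: co-stained fluorescence events, chromosome
# count anchors, population structure and ground truth labels.

#' Default cytotype panel of a mixed-ploidy polyploid complex
#'
#' Returns the eight genome-size groups used throughout the package as the
#' default simulation scenario: one diploid, two tetraploid, one pentaploid,
#' three hexaploid and one heptaploid group of a complex with monoploid
#' chromosome number x = 7. Means and standard deviations are in picograms
#' (2C-values) and describe the between-individual spread of true genome
#' size within a group. Prevalences are the package's own default mixing
#' proportions (the field proportions are not published); they emphasise the
#' common hexaploid groups and keep the odd-ploidy groups rare.
#'
#' @return A `data.frame` with columns `label`, `ploidy`, `gs_mean`, `gs_sd`
#'   and `prevalence` (summing to 1).
#' @examples
#' default_cytotypes()
#' @export
default_cytotypes <- function() {
  data.frame(
    label      = c("2x", "4xA", "4xB", "5x", "6xA", "6xB", "6xC", "7x"),
    ploidy     = c(2L, 4L, 4L, 5L, 6L, 6L, 6L, 7L),
    gs_mean    = c(2.587, 5.265, 5.966, 6.445, 7.405, 7.752, 8.196, 8.643),
    gs_sd      = c(0.036, 0.147, 0.128, 0.173, 0.095, 0.101, 0.132, 0.100),
    prevalence = c(0.10, 0.17, 0.03, 0.03, 0.04, 0.12, 0.43, 0.08),
    stringsAsFactors = FALSE
  )
}

validate_cytotypes <- function(cytotypes) {
  stopifnot(is.data.frame(cytotypes))
  need <- c("label", "ploidy", "gs_mean", "gs_sd", "prevalence")
  miss <- setdiff(need, names(cytotypes))
  if (length(miss)) stop("cytotype table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cytotypes$label)) stop("cytotype labels must be unique")
  if (any(cytotypes$gs_mean <= 0)) stop("gs_mean must be positive")
  if (any(cytotypes$gs_sd <= 0)) stop("gs_sd must be positive")
  if (any(cytotypes$ploidy < 1 | cytotypes$ploidy != round(cytotypes$ploidy)))
    stop("ploidy must be a positive integer")
  if (any(cytotypes$prevalence < 0))
    stop("prevalences must be non-negative")
  if (abs(sum(cytotypes$prevalence) - 1) > 1e-8)
    stop("prevalences must sum to 1 (got ", format(sum(cytotypes$prevalence)), ")")
  invisible(cytotypes)
}

# Deterministic hierarchical seed derivation: children of one master seed are
# reproducible in isolation (re-simulating individual i alone gives the same
# events as inside the full study). Arithmetic stays below 2^53, result < 2^31.
child_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(seed) %% m)
  for (i in as.double(index)) s <- (s * 1103515.0 + i * 12345.0 + 1.0) %% m
  as.integer(s)
}

# Run `expr` under a local RNG stream seeded with `seed` (NULL = use the
# current stream), restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate fluorescence events for one co-stained FCM analysis
#'
#' Generates per-particle fluorescence values on an arbitrary linear channel
#' scale for a single analysis in which the sample is co-chopped and co-stained
#' with an internal standard of known genome size. The standard peak is
#' centred at `reference_channel`; the sample peak at
#' `reference_channel * true_gs / standard_gs` (only the ratio of peak means
#' carries information, so the channel scale is arbitrary). Each peak is
#' Gaussian with relative standard deviation `cv/100`. A fraction
#' `debris_fraction` of events is drawn from a decaying (truncated
#' exponential) background over the channels below the lower peak, emulating
#' the debris shoulder of chopped plant tissue.
#'
#' @param true_gs True 2C genome size of the sample, pg.
#' @param standard_gs 2C genome size of the internal standard, pg.
#' @param cv_sample,cv_standard Peak coefficients of variation, percent.
#' @param n_particles Number of events recorded (default 3500).
#' @param debris_fraction Fraction of events that are debris, in `[0, 1)`.
#' @param sample_fraction Fraction of non-debris events belonging to the
#'   sample peak (the rest are standard).
#' @param reference_channel Channel position of the standard peak centre.
#' @param sample_id Identifier stored with the events.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `event_set`: a list with `sample_id`, `channel`
#'   (numeric vector of length `n_particles`) and `truth` (per-event label,
#'   one of `"sample"`, `"standard"`, `"debris"`; generator ground truth,
#'   never used by the evaluation code).
#' @examples
#' ev <- simulate_events(8.196, seed = 1)
#' mean(ev$channel[ev$truth == "sample"]) / mean(ev$channel[ev$truth == "standard"])
#' @export
simulate_events <- function(true_gs, standard_gs = 3.38,
                            cv_sample = 1.5, cv_standard = 1.5,
                            n_particles = 3500, debris_fraction = 0.2,
                            sample_fraction = 0.5, reference_channel = 200,
                            sample_id = "sample", seed = NULL) {
  if (!is.numeric(true_gs) || length(true_gs) != 1 || true_gs <= 0)
    stop("true_gs must be a single positive genome size in pg")
  if (standard_gs <= 0) stop("standard_gs must be positive")
  if (n_particles < 1) stop("n_particles must be positive")
  if (cv_sample < 0 || cv_standard < 0) stop("CVs must be non-negative")
  if (debris_fraction < 0 || debris_fraction >= 1)
    stop("debris_fraction must be in [0, 1)")
  if (sample_fraction <= 0 || sample_fraction >= 1)
    stop("sample_fraction must be in (0, 1)")

  with_seed(seed, {
    sample_centre <- reference_channel * true_gs / standard_gs
    n_debris <- stats::rbinom(1, n_particles, debris_fraction)
    n_signal <- n_particles - n_debris
    n_sample <- stats::rbinom(1, n_signal, sample_fraction)
    n_standard <- n_signal - n_sample

    ch_sample <- stats::rnorm(n_sample, sample_centre,
                              sample_centre * cv_sample / 100)
    ch_standard <- stats::rnorm(n_standard, reference_channel,
                                reference_channel * cv_standard / 100)
    # Debris: truncated exponential spanning the low channels, kept below the
    # lower of the two peaks so it forms a left shoulder, not a third peak.
    lo_peak <- min(sample_centre, reference_channel)
    debris_max <- 0.8 * lo_peak
    debris_scale <- debris_max / 4
    u <- stats::runif(n_debris)
    ch_debris <- -debris_scale * log(1 - u * (1 - exp(-debris_max / debris_scale)))

    channel <- c(ch_sample, ch_standard, ch_debris)
    truth <- c(rep("sample", n_sample), rep("standard", n_standard),
               rep("debris", n_debris))
    ord <- sample.int(length(channel))
    structure(
      list(sample_id = sample_id,
           channel = pmax(channel[ord], 0),
           truth = truth[ord]),
      class = "event_set"
    )
  })
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set> ", x$sample_id, ": ", length(x$channel), " events (",
      sum(x$truth == "debris"), " debris)\n", sep = "")
  invisible(x)
}

#' Build a scenario configuration for a synthetic FCM study
#'
#' Collects every knob of the synthetic study design: the cytotype panel,
#' sampling design (number of populations, individuals per population),
#' per-population cytotype mixtures, habitat assignment, acquisition settings
#' (particles per analysis, peak CVs, debris), the chromosome-counted anchor
#' subset, and injected quality failures. Defaults emulate a field survey of
#' a mixed-ploidy halophyte complex: 133 populations of 15 individuals,
#' 3500 particles per analysis, 1.5% peak CVs, 39 chromosome-counted
#' anchors, and a 15% rate of degraded (high-CV) analyses so the quality
#' filter has realistic work to do.
#'
#' @param cytotypes Cytotype table as from [default_cytotypes()].
#' @param n_populations Number of populations.
#' @param individuals_per_population Individuals sampled per population.
#' @param mixture_matrix Optional `n_populations x nrow(cytotypes)` matrix of
#'   per-population cytotype composition probabilities (rows sum to 1).
#'   `NULL` generates one with [make_mixture_matrix()] at `mixed_fraction`.
#' @param mixed_fraction Fraction of populations generated as mixed when
#'   `mixture_matrix` is `NULL`.
#' @param anthropogenic_propensity Named per-cytotype probability scale for a
#'   population being anthropogenic; a population's probability is the
#'   minimum over the cytotypes present in its mixture, so groups with
#'   propensity 0 never occur in anthropogenic habitats.
#' @param n_particles Events per analysis.
#' @param cv_sample,cv_standard Peak CVs, percent.
#' @param debris_fraction Debris fraction per analysis.
#' @param qc_fail_rate Fraction of analyses generated with inflated CVs
#'   (drawn uniformly from `qc_fail_cv_range`), emulating degraded runs.
#' @param qc_fail_cv_range Range of inflated CVs, percent.
#' @param anchor_count Number of chromosome-counted individuals.
#' @param standard_gs Internal standard 2C genome size, pg.
#' @param reference_channel Channel of the standard peak centre.
#' @param seed Master seed; all study randomness derives from it.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(cytotypes = default_cytotypes(),
                            n_populations = 133,
                            individuals_per_population = 15,
                            mixture_matrix = NULL,
                            mixed_fraction = 0.38,
                            anthropogenic_propensity = c(
                              "2x" = 0, "4xA" = 0.15, "4xB" = 0.15, "5x" = 0,
                              "6xA" = 0.3, "6xB" = 0.4, "6xC" = 0.6, "7x" = 0.3),
                            n_particles = 3500,
                            cv_sample = 1.5, cv_standard = 1.5,
                            debris_fraction = 0.2,
                            qc_fail_rate = 0.15,
                            qc_fail_cv_range = c(3.2, 5),
                            anchor_count = 39,
                            standard_gs = 3.38,
                            reference_channel = 200,
                            seed = 1L) {
  validate_cytotypes(cytotypes)
  if (n_populations < 1) stop("n_populations must be at least 1")
  if (individuals_per_population < 1)
    stop("individuals_per_population must be at least 1")
  if (n_particles < 100) stop("n_particles must be at least 100")
  if (debris_fraction < 0 || debris_fraction >= 1)
    stop("debris_fraction must be in [0, 1)")
  if (qc_fail_rate < 0 || qc_fail_rate >= 1)
    stop("qc_fail_rate must be in [0, 1)")
  n_total <- n_populations * individuals_per_population
  if (anchor_count > n_total)
    stop("anchor_count (", anchor_count, ") exceeds total individuals (",
         n_total, ")")
  if (!is.null(mixture_matrix)) {
    mixture_matrix <- as.matrix(mixture_matrix)
    if (nrow(mixture_matrix) != n_populations ||
        ncol(mixture_matrix) != nrow(cytotypes))
      stop("mixture_matrix must be n_populations x n_cytotypes")
    if (any(mixture_matrix < 0) ||
        any(abs(rowSums(mixture_matrix) - 1) > 1e-8))
      stop("mixture_matrix rows must be non-negative and sum to 1")
  }
  if (is.null(names(anthropogenic_propensity)) ||
      !all(cytotypes$label %in% names(anthropogenic_propensity))) {
    # fall back to a flat propensity for user-defined panels
    anthropogenic_propensity <- stats::setNames(
      rep(0.4, nrow(cytotypes)), cytotypes$label)
  }
  structure(
    list(cytotypes = cytotypes,
         n_populations = as.integer(n_populations),
         individuals_per_population = as.integer(individuals_per_population),
         mixture_matrix = mixture_matrix,
         mixed_fraction = mixed_fraction,
         anthropogenic_propensity = anthropogenic_propensity,
         n_particles = as.integer(n_particles),
         cv_sample = cv_sample, cv_standard = cv_standard,
         debris_fraction = debris_fraction,
         qc_fail_rate = qc_fail_rate,
         qc_fail_cv_range = qc_fail_cv_range,
         anchor_count = as.integer(anchor_count),
         standard_gs = standard_gs,
         reference_channel = reference_channel,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n",
      "  cytotypes: ", paste(x$cytotypes$label, collapse = ", "), "\n",
      "  populations: ", x$n_populations, " x ",
      x$individuals_per_population, " individuals\n",
      "  particles/analysis: ", x$n_particles,
      ", debris ", x$debris_fraction,
      ", CVs ", x$cv_sample, "/", x$cv_standard, "%\n",
      "  anchors: ", x$anchor_count, ", qc_fail_rate ", x$qc_fail_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate per-population cytotype composition probabilities
#'
#' A fraction `mixed_fraction` of populations is generated as mixed: the
#' population's cytotypes are 2 or 3 groups drawn by prevalence, with
#' composition weights drawn uniformly on the simplex and renormalised. The
#' remaining populations are pure, with the single cytotype drawn by
#' prevalence.
#'
#' @param cytotypes Cytotype table.
#' @param n_populations Number of rows to generate.
#' @param mixed_fraction Fraction of mixed populations.
#' @param seed Integer seed (`NULL` = current stream).
#' @return A matrix of composition probabilities, rows summing to 1, with
#'   cytotype labels as column names.
#' @export
make_mixture_matrix <- function(cytotypes, n_populations,
                                mixed_fraction = 0.38, seed = NULL) {
  validate_cytotypes(cytotypes)
  k <- nrow(cytotypes)
  with_seed(seed, {
    m <- matrix(0, n_populations, k, dimnames = list(NULL, cytotypes$label))
    n_mixed <- round(mixed_fraction * n_populations)
    is_mixed <- seq_len(n_populations) %in%
      sample.int(n_populations, n_mixed)
    n_pos <- sum(cytotypes$prevalence > 0)
    for (i in seq_len(n_populations)) {
      if (is_mixed[i] && n_pos >= 2) {
        n_groups <- sample(2:min(3, n_pos), 1)
        groups <- sample.int(k, n_groups, prob = cytotypes$prevalence)
        w <- stats::runif(n_groups, 0.15, 1)
        m[i, groups] <- w / sum(w)
      } else {
        m[i, sample.int(k, 1, prob = cytotypes$prevalence)] <- 1
      }
    }
    m
  })
}

#' Simulate a complete synthetic FCM study
#'
#' Draws the whole study implied by a [scenario_config()]: population
#' habitats, per-individual cytotypes and true genome sizes, per-analysis
#' fluorescence events (via [simulate_events()]), a chromosome-counted anchor
#' subset covering every cytotype present, and the ground-truth table.
#' Per-individual true genome size is drawn from
#' `Normal(gs_mean, gs_sd)` of its cytotype, so the panel's standard
#' deviations act as between-individual spread, while the configured CVs act
#' within an analysis. A fraction `qc_fail_rate` of analyses is generated
#' with inflated CVs and should be removed by the downstream quality filter;
#' anchors are drawn from the non-degraded individuals only (chromosome
#' counting presupposes a usable measurement).
#'
#' @param config A `scenario_config`.
#' @return An object of class `fc_study`: a list with
#'   \describe{
#'     \item{events}{named list of `event_set`, one per individual}
#'     \item{truth}{data.frame of per-individual ground truth (`sample_id`,
#'       `population_id`, `true_group`, `true_ploidy`, `true_gs`,
#'       `cv_injected`, `is_anchor`)}
#'     \item{chromosome_counts}{data.frame `sample_id`, `two_n` for anchors}
#'     \item{populations}{data.frame `population_id`, `habitat`,
#'       `latitude`, `longitude`, `n_sampled`}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' cfg <- scenario_config(n_populations = 2, n_particles = 500, seed = 42)
#' study <- simulate_study(cfg)
#' head(study$truth)
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "scenario_config"))
    stop("config must be a scenario_config")
  ct <- config$cytotypes
  n_pop <- config$n_populations
  n_ind <- config$individuals_per_population

  mix <- config$mixture_matrix
  if (is.null(mix))
    mix <- make_mixture_matrix(ct, n_pop, config$mixed_fraction,
                               seed = child_seed(config$seed, 1))

  with_seed(child_seed(config$seed, 2), {
    # population habitats: min propensity over cytotypes present in the mix
    prop <- config$anthropogenic_propensity[ct$label]
    p_anthro <- vapply(seq_len(n_pop), function(i) {
      present <- mix[i, ] > 0
      min(prop[present])
    }, numeric(1))
    habitat <- ifelse(stats::runif(n_pop) < p_anthro,
                      "anthropogenic", "natural")
    populations <- data.frame(
      population_id = sprintf("pop%03d", seq_len(n_pop)),
      habitat = habitat,
      latitude = stats::runif(n_pop, 45, 53),
      longitude = stats::runif(n_pop, 8, 25),
      n_sampled = n_ind,
      stringsAsFactors = FALSE
    )

    # per-individual cytotype and true GS
    pop_idx <- rep(seq_len(n_pop), each = n_ind)
    group_idx <- integer(n_pop * n_ind)
    for (i in seq_len(n_pop)) {
      rows <- which(pop_idx == i)
      group_idx[rows] <- sample.int(nrow(ct), n_ind, replace = TRUE,
                                    prob = mix[i, ])
    }
    true_gs <- stats::rnorm(length(group_idx),
                            ct$gs_mean[group_idx], ct$gs_sd[group_idx])
    true_gs <- pmax(true_gs, 0.05) # guard against absurd negative draws
    cv_injected <- stats::runif(length(group_idx)) < config$qc_fail_rate

    truth <- data.frame(
      sample_id = sprintf("ind%04d", seq_along(group_idx)),
      population_id = populations$population_id[pop_idx],
      true_group = ct$label[group_idx],
      true_ploidy = ct$ploidy[group_idx],
      true_gs = true_gs,
      cv_injected = cv_injected,
      is_anchor = FALSE,
      stringsAsFactors = FALSE
    )

    # anchors: representative coverage — several counted individuals per
    # cytotype present (a single anchor cannot anchor a group robustly:
    # one boundary individual captured by a neighbouring mixture component
    # would leave the group uncovered), remainder allocated proportionally
    # to group frequency; sampled uniformly within group among
    # non-degraded individuals
    eligible <- which(!cv_injected)
    pool <- if (length(eligible)) eligible else seq_along(group_idx)
    groups_present <- sort(unique(group_idx[pool]))
    freq <- tabulate(group_idx[pool], nbins = nrow(ct))[groups_present]
    floor_per_group <- pmin(freq, pmin(3L, config$anchor_count %/%
                                         max(1L, length(groups_present))))
    alloc <- pmax(floor_per_group,
                  round(config$anchor_count * freq / sum(freq)))
    # trim/grow to hit anchor_count exactly, never below the floor
    while (sum(alloc) > config$anchor_count && any(alloc > floor_per_group)) {
      j <- which.max(alloc - floor_per_group); alloc[j] <- alloc[j] - 1L
    }
    while (sum(alloc) < config$anchor_count) {
      j <- which.max(freq / alloc); alloc[j] <- alloc[j] + 1L
    }
    anchor_rows <- integer(0)
    for (g in seq_along(groups_present)) {
      rows <- pool[group_idx[pool] == groups_present[g]]
      take <- min(alloc[g], length(rows))
      anchor_rows <- c(anchor_rows,
                       if (length(rows) == 1) rows
                       else sample(rows, take))
    }
    truth$is_anchor[anchor_rows] <- TRUE
    chromosome_counts <- data.frame(
      sample_id = truth$sample_id[anchor_rows],
      two_n = 7L * truth$true_ploidy[anchor_rows],
      stringsAsFactors = FALSE
    )
    chromosome_counts <-
      chromosome_counts[order(chromosome_counts$sample_id), , drop = FALSE]
    rownames(chromosome_counts) <- NULL

    events <- vector("list", nrow(truth))
    names(events) <- truth$sample_id
    for (i in seq_len(nrow(truth))) {
      if (cv_injected[i]) {
        cvs <- stats::runif(2, config$qc_fail_cv_range[1],
                            config$qc_fail_cv_range[2])
      } else {
        cvs <- c(config$cv_sample, config$cv_standard)
      }
      events[[i]] <- simulate_events(
        true_gs = truth$true_gs[i],
        standard_gs = config$standard_gs,
        cv_sample = cvs[1], cv_standard = cvs[2],
        n_particles = config$n_particles,
        debris_fraction = config$debris_fraction,
        reference_channel = config$reference_channel,
        sample_id = truth$sample_id[i],
        seed = child_seed(config$seed, c(3, i))
      )
    }

    structure(
      list(events = events, truth = truth,
           chromosome_counts = chromosome_counts,
           populations = populations, config = config),
      class = "fc_study"
    )
  })
}

#' @export
print.fc_study <- function(x, ...) {
  cat("<fc_study> ", nrow(x$truth), " individuals in ",
      nrow(x$populations), " populations; ",
      nrow(x$chromosome_counts), " chromosome-counted anchors\n", sep = "")
  print(table(x$truth$true_group))
  invisible(x)
}
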