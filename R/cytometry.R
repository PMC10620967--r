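# Evaluation of FCM analyses: histogramming, peak detection, per-peak
# statistics, genome size computation and the CV quality filter.

#' Histogram fluorescence events
#'
#' Bins per-particle channel values into `n_bins` equal-width, half-open
#' `[low, high)` intervals spanning `[0, max(channel))`; the maximum value is
#' included in the last bin so counts are conserved.
#'
#' @param events An `event_set` (or a bare numeric vector of channel values).
#' @param n_bins Number of bins, at least 32.
#' @return An object of class `fc_histogram`: list with `counts`, `breaks`
#'   (length `n_bins + 1`), `mids` and `n_events`.
#' @export
build_histogram <- function(events, n_bins = 256) {
  values <- if (inherits(events, "event_set")) events$channel else events
  if (length(values) == 0) stop("cannot histogram an empty event set")
  if (any(values < 0)) stop("channel values must be non-negative")
  if (n_bins < 32) stop("n_bins must be at least 32")
  hi <- max(values)
  if (hi == 0) hi <- 1
  breaks <- seq(0, hi * (1 + 1e-9), length.out = n_bins + 1)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(counts = counts, breaks = breaks,
         mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
         n_events = length(values)),
    class = "fc_histogram"
  )
}

#' @export
print.fc_histogram <- function(x, ...) {
  cat("<fc_histogram> ", length(x$counts), " bins over [0, ",
      format(max(x$breaks), digits = 4), "), ", x$n_events, " events\n",
      sep = "")
  invisible(x)
}

#' Detect fluorescence peaks in a histogram
#'
#' Scans a lightly smoothed (3-bin running mean) histogram for local maxima
#' whose *topographic prominence* — height above the highest saddle
#' separating the maximum from higher terrain — exceeds `min_prominence`
#' times the global maximum. Prominence, not raw height, is what excludes
#' the debris shoulder: noise bumps on a decaying background always have
#' slightly higher terrain upslope behind a shallow saddle, so their
#' prominence stays at noise level however tall the background is. Windows
#' are then expanded around each retained maximum until the counts fall
#' below `drop_frac` of the peak height or start rising again (a valley
#' between adjacent peaks).
#'
#' @param histogram An `fc_histogram`.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   tallest bin.
#' @param min_events Minimum events inside the window for the peak to be
#'   kept.
#' @param drop_frac Fraction of peak height at which the window closes.
#' @return A data.frame of windows ordered by channel, one row per peak:
#'   `peak_channel`, `window_low`, `window_high` (half-open channel
#'   interval), `n_events`.
#' @export
detect_peaks <- function(histogram, min_prominence = 0.05, min_events = 50,
                         drop_frac = 0.02) {
  stopifnot(inherits(histogram, "fc_histogram"))
  counts <- histogram$counts
  n <- length(counts)
  if (n < 3 || all(counts == 0))
    return(empty_windows())
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[c(1, n)] <- counts[c(1, n)]
  sm <- as.numeric(sm)
  thresh <- min_prominence * max(sm)

  # candidate maxima: strictly above both neighbours (plateaus: left edge)
  cand <- which(sm[-c(1, n)] >= sm[-c(n - 1, n)] &
                  sm[-c(1, n)] > sm[-c(1, 2)]) + 1
  cand <- cand[cand > 2]
  if (!length(cand)) return(empty_windows())
  cand <- cand[prominence(sm, cand) >= thresh]
  if (!length(cand)) return(empty_windows())
  cand <- cand[order(sm[cand], decreasing = TRUE)]

  taken <- rep(FALSE, n)
  out <- list()
  for (p in cand) {
    if (taken[p]) next
    height <- sm[p]
    # expand until counts drop below drop_frac of the height, another peak's
    # territory is reached, or counts rise again after a genuine valley
    # (below half height) — small rises near the top are shot noise
    lo <- p
    while (lo > 1 && !taken[lo - 1] && sm[lo - 1] > drop_frac * height &&
           !(sm[lo - 1] > sm[lo] && sm[lo] < 0.5 * height)) lo <- lo - 1
    hi <- p
    while (hi < n && !taken[hi + 1] && sm[hi + 1] > drop_frac * height &&
           !(sm[hi + 1] > sm[hi] && sm[hi] < 0.5 * height)) hi <- hi + 1
    n_ev <- sum(counts[lo:hi])
    if (n_ev < min_events) next
    taken[lo:hi] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      peak_channel = histogram$mids[p],
      window_low = histogram$breaks[lo],
      window_high = histogram$breaks[hi + 1],
      n_events = n_ev
    )
  }
  if (!length(out)) return(empty_windows())
  res <- do.call(rbind, out)
  res <- res[order(res$peak_channel), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Topographic prominence of each candidate maximum: height minus the key
# saddle, where the key saddle is, per side, the minimum level on the path
# to the nearest strictly higher bin (or the global minimum of that side if
# none is higher), and overall the higher of the two side-saddles. The
# global maximum has prominence equal to its height.
prominence <- function(sm, cand) {
  n <- length(sm)
  vapply(cand, function(p) {
    h <- sm[p]
    saddle_side <- function(idx) {
      if (!length(idx)) return(-Inf)
      run_min <- h
      for (i in idx) {
        if (sm[i] > h) return(run_min)
        if (sm[i] < run_min) run_min <- sm[i]
      }
      -Inf # no higher terrain on this side
    }
    left <- saddle_side(rev(seq_len(p - 1)))
    right <- saddle_side(if (p < n) (p + 1):n else integer(0))
    key <- max(left, right)
    if (!is.finite(key)) h else h - key
  }, numeric(1))
}

empty_windows <- function() {
  data.frame(peak_channel = numeric(0), window_low = numeric(0),
             window_high = numeric(0), n_events = numeric(0))
}

#' Estimate peak statistics from events inside a window
#'
#' Mean fluorescence is the arithmetic mean of in-window values; the CV is
#' `100 * SD / mean` using the population standard deviation convention
#' (divide by n, not n - 1) — the events are the full recorded peak, not a
#' subsample.
#'
#' @param events An `event_set` or numeric channel vector.
#' @param window Numeric `c(low, high)`: half-open channel interval.
#' @param min_events Minimum in-window events required.
#' @return A one-row data.frame `mean_fluorescence`, `cv`, `event_count`,
#'   `window_low`, `window_high`, or `NULL` (with a message) when the peak
#'   has fewer than `min_events` events.
#' @examples
#' estimate_peak_stats(c(198, 200, 202), c(150, 250), min_events = 1)
#' @export
estimate_peak_stats <- function(events, window, min_events = 50) {
  values <- if (inherits(events, "event_set")) events$channel else events
  stopifnot(length(window) == 2, window[1] < window[2])
  inw <- values[values >= window[1] & values < window[2]]
  if (length(inw) < min_events) {
    message("peak in [", format(window[1]), ", ", format(window[2]),
            ") discarded: ", length(inw), " < ", min_events, " events")
    return(NULL)
  }
  m <- mean(inw)
  s <- sqrt(mean((inw - m)^2))
  data.frame(mean_fluorescence = m, cv = 100 * s / m,
             event_count = length(inw),
             window_low = window[1], window_high = window[2])
}

#' Genome size from the sample/standard fluorescence ratio
#'
#' The 2C genome size of the sample is the ratio of the mean fluorescence of
#' the sample peak to the mean fluorescence of the internal standard peak,
#' multiplied by the genome size of the internal standard. The result is
#' scale-free: any linear channel calibration cancels in the ratio.
#'
#' @param sample_mean,standard_mean Peak mean fluorescences, channel units.
#' @param standard_gs 2C genome size of the internal standard, pg
#'   (default 3.38).
#' @return Genome size in pg.
#' @examples
#' compute_gs(485, 200)        # 8.1965
#' compute_gs(200, 200)        # exactly the standard, 3.38
#' @export
compute_gs <- function(sample_mean, standard_mean, standard_gs = 3.38) {
  if (any(sample_mean <= 0) || any(standard_mean <= 0))
    stop("peak means must be positive")
  if (standard_gs <= 0) stop("standard_gs must be positive")
  sample_mean / standard_mean * standard_gs
}

#' Evaluate one FCM analysis into a sample measurement
#'
#' Runs the histogram/peak pipeline on one analysis: detects peaks,
#' identifies the internal standard as the detected peak nearest the
#' configured reference channel, takes the largest remaining peak as the
#' sample, and computes the genome size. When only one peak is found the
#' sample and standard are taken to coincide (genome size equal to the
#' standard) and the measurement is flagged, since sample/standard overlap
#' cannot be resolved from a single histogram.
#'
#' @param events An `event_set`.
#' @param standard_gs Internal standard 2C value, pg.
#' @param reference_channel Expected channel of the standard peak.
#' @param n_bins,min_prominence,min_events,drop_frac Passed to
#'   [build_histogram()] / [detect_peaks()].
#' @return One-row data.frame: `sample_id`, `n_events`, `n_peaks`,
#'   `sample_mean`, `sample_cv`, `sample_n`, `standard_mean`, `standard_cv`,
#'   `standard_n`, `genome_size`, `note`.
#' @export
evaluate_events <- function(events, standard_gs = 3.38,
                            reference_channel = 200, n_bins = 256,
                            min_prominence = 0.05, min_events = 50,
                            drop_frac = 0.02) {
  stopifnot(inherits(events, "event_set"))
  h <- build_histogram(events, n_bins)
  pk <- detect_peaks(h, min_prominence, min_events, drop_frac)
  base <- data.frame(sample_id = events$sample_id,
                     n_events = length(events$channel),
                     n_peaks = nrow(pk),
                     sample_mean = NA_real_, sample_cv = NA_real_,
                     sample_n = NA_integer_,
                     standard_mean = NA_real_, standard_cv = NA_real_,
                     standard_n = NA_integer_,
                     genome_size = NA_real_, note = "",
                     stringsAsFactors = FALSE)
  if (nrow(pk) == 0) {
    base$note <- "no peaks detected"
    return(base)
  }
  stats_list <- lapply(seq_len(nrow(pk)), function(i)
    estimate_peak_stats(events, c(pk$window_low[i], pk$window_high[i]),
                        min_events = min_events))
  keep <- !vapply(stats_list, is.null, logical(1))
  pk <- pk[keep, , drop = FALSE]
  stats_df <- do.call(rbind, stats_list[keep])
  if (is.null(stats_df) || nrow(stats_df) == 0) {
    base$note <- "no peaks above minimum size"
    base$n_peaks <- 0L
    return(base)
  }
  i_std <- which.min(abs(stats_df$mean_fluorescence - reference_channel))
  std <- stats_df[i_std, ]
  base$standard_mean <- std$mean_fluorescence
  base$standard_cv <- std$cv
  base$standard_n <- std$event_count
  if (nrow(stats_df) == 1) {
    # overlapping sample and standard peaks: ratio 1 by construction
    base$sample_mean <- std$mean_fluorescence
    base$sample_cv <- std$cv
    base$sample_n <- std$event_count
    base$genome_size <- standard_gs
    base$note <- "single peak: sample and standard overlap; GS set to standard"
    warning("sample and standard peaks overlap for ", events$sample_id,
            "; genome size reported as the standard value", call. = FALSE)
  } else {
    rest <- stats_df[-i_std, , drop = FALSE]
    smp <- rest[which.max(rest$event_count), ]
    base$sample_mean <- smp$mean_fluorescence
    base$sample_cv <- smp$cv
    base$sample_n <- smp$event_count
    base$genome_size <- compute_gs(smp$mean_fluorescence,
                                   std$mean_fluorescence, standard_gs)
    if (nrow(stats_df) > 2)
      base$note <- paste0(nrow(stats_df), " peaks detected; largest ",
                          "non-standard peak taken as sample")
  }
  base$n_peaks <- nrow(stats_df)
  base
}

#' Evaluate every analysis of a synthetic or loaded study
#'
#' @param study An `fc_study`, or a named list of `event_set`s.
#' @param ... Passed to [evaluate_events()].
#' @return A data.frame of measurements, one row per analysis, joined with
#'   `population_id` when the input is an `fc_study`.
#' @export
evaluate_study <- function(study, ...) {
  events <- if (inherits(study, "fc_study")) study$events else study
  args <- list(...)
  if (inherits(study, "fc_study")) {
    if (is.null(args$standard_gs)) args$standard_gs <- study$config$standard_gs
    if (is.null(args$reference_channel))
      args$reference_channel <- study$config$reference_channel
  }
  rows <- lapply(events, function(ev)
    do.call(evaluate_events, c(list(ev), args)))
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL
  if (inherits(study, "fc_study")) {
    meas$population_id <- study$truth$population_id[
      match(meas$sample_id, study$truth$sample_id)]
  }
  meas
}

#' Quality filter on peak coefficients of variation
#'
#' Partitions measurements into accepted and rejected analyses. A
#' measurement passes iff every retained peak CV (sample and standard) is
#' strictly below `cv_max`; analyses with missing genome size (no usable
#' peaks) fail. The threshold applies to both peaks: a noisy standard peak
#' corrupts the ratio just as a noisy sample peak does.
#'
#' @param measurements Data.frame as from [evaluate_study()].
#' @param cv_max CV threshold in percent (default 2.5, strict `<`).
#' @return A list with elements `passed` and `failed`; both carry `qc_pass`
#'   and `qc_reason` columns, and together partition the input.
#' @export
qc_filter <- function(measurements, cv_max = 2.5) {
  if (cv_max <= 0) stop("cv_max must be positive")
  m <- measurements
  reason <- character(nrow(m))
  ok <- rep(TRUE, nrow(m))
  bad_gs <- is.na(m$genome_size)
  ok[bad_gs] <- FALSE
  reason[bad_gs] <- "no usable peaks"
  cv_bad <- !bad_gs & (m$sample_cv >= cv_max | m$standard_cv >= cv_max)
  ok[cv_bad] <- FALSE
  reason[cv_bad] <- sprintf("CV >= %g%% (sample %.2f, standard %.2f)",
                            cv_max, m$sample_cv[cv_bad],
                            m$standard_cv[cv_bad])
  m$qc_pass <- ok
  m$qc_reason <- reason
  list(passed = m[ok, , drop = FALSE],
       failed = m[!ok, , drop = FALSE])
}
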