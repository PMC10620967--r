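# Reading and writing the pipeline's tabular interchange formats.

#' Write events as delimited tabular text
#'
#' One row per particle: `sample_id`, `channel_value`, `truth_label`.
#' Ground-truth labels travel with the events so downstream validation can
#' compare against them; they are never read by the evaluation code.
#'
#' @param events A single `event_set` or a (possibly named) list of them.
#' @param path Output CSV path.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "event_set")) events <- list(events)
  df <- do.call(rbind, lapply(events, function(ev)
    data.frame(sample_id = ev$sample_id, channel_value = ev$channel,
               truth_label = ev$truth, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read events from delimited tabular text
#'
#' @param path CSV with columns `sample_id`, `channel_value` and optionally
#'   `truth_label`.
#' @return Named list of `event_set` objects, one per sample.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "channel_value")
  if (!all(need %in% names(df)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$truth_label)) df$truth_label <- NA_character_
  split_idx <- split(seq_len(nrow(df)), df$sample_id)
  lapply(split_idx, function(i)
    structure(list(sample_id = df$sample_id[i[1]],
                   channel = df$channel_value[i],
                   truth = df$truth_label[i]),
              class = "event_set"))
}

#' Read pre-evaluated per-sample peak statistics
#'
#' For users with instrument-software exports instead of raw events: a CSV
#' with one row per analysis (`sample_id`, `sample_mean`, `sample_cv`,
#' `standard_mean`, `standard_cv`, optionally `population_id`). Genome sizes
#' are computed from the peak means via [compute_gs()].
#'
#' @param path CSV path.
#' @param standard_gs Internal standard 2C value, pg.
#' @return Measurements data.frame compatible with [qc_filter()].
#' @export
read_peak_stats_csv <- function(path, standard_gs = 3.38) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sample_mean", "sample_cv",
            "standard_mean", "standard_cv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak statistics file lacks columns: ", paste(miss, collapse = ", "))
  df$genome_size <- compute_gs(df$sample_mean, df$standard_mean, standard_gs)
  df$note <- ""
  df
}

#' Read a scenario configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [scenario_config()]; the
#' `cytotypes` key is a list of records with `label`, `ploidy`, `gs_mean`,
#' `gs_sd`, `prevalence`. Omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$cytotypes)) {
    args$cytotypes <- do.call(rbind, lapply(raw$cytotypes, function(r)
      data.frame(label = r$label, ploidy = as.integer(r$ploidy),
                 gs_mean = r$gs_mean, gs_sd = r$gs_sd,
                 prevalence = r$prevalence, stringsAsFactors = FALSE)))
  }
  if (!is.null(raw$anthropogenic_propensity))
    args$anthropogenic_propensity <- unlist(raw$anthropogenic_propensity)
  if (!is.null(raw$mixture_matrix))
    args$mixture_matrix <- do.call(rbind, raw$mixture_matrix)
  do.call(scenario_config, args)
}

write_csv_quiet <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
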