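# End-to-end orchestration: simulate/load -> evaluate -> QC -> mixture fit
# and selection -> anchored delimitation -> assignment -> population summary.

#' Run the full cytotype-inference pipeline
#'
#' Orchestrates every stage on either a synthetic study (pass a
#' `scenario_config`) or pre-simulated/loaded inputs (pass an `fc_study`).
#' Stage outputs are returned and, when `out_dir` is given, written as CSVs:
#' measurements (with QC columns), mixture parameters, per-sample
#' responsibilities, groups, assignments, population summaries,
#' intersection counts, habitat association, and a YAML run report carrying
#' the configuration, seed, package version and headline counts.
#'
#' @param config A `scenario_config` or an `fc_study`.
#' @param out_dir Output directory (created); `NULL` writes nothing.
#' @param k_candidates Component numbers to fit and compare (default 8, 9).
#' @param cv_max QC threshold on peak CVs, percent (default 2.5, strict).
#' @param n_restarts,em_tol,max_iter EM settings, see [fit_gmm()].
#' @param n_perm Permutations for the habitat diagnostic.
#' @param seed Seed for EM restarts and the permutation test; defaults to
#'   the study seed.
#' @return A list of class `fc_pipeline`: `study`, `measurements`, `qc`,
#'   `selection`, `model`, `mapping`, `groups`, `assignments`,
#'   `population_summary`, `intersections`, `habitat`, `report`.
#' @examples
#' \donttest{
#' cfg <- scenario_config(n_populations = 8, n_particles = 1500, seed = 7)
#' res <- run_pipeline(cfg, k_candidates = c(8, 9))
#' res$report
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, k_candidates = c(8, 9),
                         cv_max = 2.5, n_restarts = 4, em_tol = 1e-8,
                         max_iter = 1e6, n_perm = 10000, seed = NULL) {
  study <- if (inherits(config, "fc_study")) config
           else if (inherits(config, "scenario_config")) simulate_study(config)
           else stop("config must be a scenario_config or fc_study")
  if (is.null(seed)) seed <- study$config$seed

  message("evaluating ", length(study$events), " analyses ...")
  measurements <- evaluate_study(study)
  qc <- qc_filter(measurements, cv_max)
  passed <- qc$passed
  if (nrow(passed) < max(k_candidates) + 1)
    stop("pipeline aborted: only ", nrow(passed),
         " analyses passed QC; cannot fit k = ", max(k_candidates))

  message("fitting mixtures for k in {",
          paste(k_candidates, collapse = ", "), "} on ",
          nrow(passed), " genome sizes ...")
  candidates <- lapply(seq_along(k_candidates), function(i)
    fit_gmm(passed$genome_size, k_candidates[i], max_iter = max_iter,
            tol = em_tol, n_restarts = n_restarts,
            seed = child_seed(seed, c(100, i))))
  selection <- select_model(candidates)
  model <- selection$model

  anchors <- merge(study$chromosome_counts,
                   passed[, c("sample_id", "genome_size")],
                   by = "sample_id")
  names(anchors)[names(anchors) == "genome_size"] <- "gs"
  if (!nrow(anchors))
    stop("pipeline aborted: no chromosome-counted anchor passed QC")

  # a redundant component that captured no anchor (typically a vestigial
  # twin of a real group) cannot be delimited and duplicates structure
  # another component carries: drop it rather than abort. Components
  # without anchors that are NOT redundant still abort below — they flag
  # real groups that need chromosome counts.
  repeat {
    covered <- unique(classify(model, anchors$gs)$labels)
    uncovered <- setdiff(seq_len(model$k), covered)
    droppable <- intersect(uncovered, redundancy_test(model))
    if (!length(droppable)) break
    message("dropping ", length(droppable), " redundant anchor-free ",
            "component(s) at ",
            paste(round(model$means[droppable], 3), collapse = ", "),
            " pg before delimitation")
    keep <- setdiff(seq_len(model$k), droppable)
    model <- fc_gmm_model(model$means[keep], model$sds[keep],
                          model$weights[keep])
  }

  mapping <- map_components_to_ploidy(model, anchors)
  groups <- delimit_groups(model, mapping, anchors)
  assignments <- assign_groups(passed, groups, anchors = anchors)

  psum <- summarize_populations(assignments, study$populations)
  inter <- intersection_counts(psum)
  habitat <- habitat_association(psum, n_perm = n_perm,
                                 seed = child_seed(seed, 200))

  cls <- classify(model, passed$genome_size)
  report <- list(
    n_measured = nrow(measurements),
    n_passed_qc = nrow(passed),
    n_failed_qc = nrow(qc$failed),
    k_candidates = k_candidates,
    k_chosen = model$k,
    groups = groups$label,
    n_assigned = sum(assignments$group != "UNASSIGNED"),
    n_unassigned = sum(assignments$group == "UNASSIGNED"),
    n_populations = nrow(study$populations),
    mixed_fraction = mean(psum$summaries$is_mixed),
    seed = seed,
    package_version = as.character(utils::packageVersion("fcploidy"))
  )

  result <- structure(
    list(study = study, measurements = measurements, qc = qc,
         selection = selection, model = model, mapping = mapping,
         groups = groups, assignments = assignments,
         population_summary = psum, intersections = inter,
         habitat = habitat, report = report),
    class = "fc_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.fc_pipeline <- function(x, ...) {
  r <- x$report
  cat("<fc_pipeline>\n",
      "  measured: ", r$n_measured, "  passed QC: ", r$n_passed_qc, "\n",
      "  k chosen: ", r$k_chosen, " of {",
      paste(r$k_candidates, collapse = ", "), "}\n",
      "  groups: ", paste(r$groups, collapse = ", "), "\n",
      "  assigned: ", r$n_assigned, "  unassigned: ", r$n_unassigned, "\n",
      "  mixed populations: ", round(100 * r$mixed_fraction, 1), "%\n",
      sep = "")
  invisible(x)
}

#' Write every pipeline stage output as CSV plus a YAML run report
#'
#' @param result An `fc_pipeline`.
#' @param out_dir Directory to create and populate.
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "fc_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- rbind(result$qc$passed, result$qc$failed)
  write_csv_quiet(m[order(m$sample_id), ], file.path(out_dir, "measurements.csv"))
  model <- result$model
  write_csv_quiet(
    data.frame(component = seq_len(model$k), mean = model$means,
               sd = model$sds, weight = model$weights),
    file.path(out_dir, "model.csv"))
  cls <- classify(model, result$qc$passed$genome_size)
  resp <- as.data.frame(cls$responsibilities)
  names(resp) <- paste0("comp", seq_len(model$k))
  resp <- cbind(sample_id = result$qc$passed$sample_id, resp)
  write_csv_quiet(resp, file.path(out_dir, "responsibilities.csv"))
  write_csv_quiet(result$groups, file.path(out_dir, "groups.csv"))
  write_csv_quiet(result$assignments, file.path(out_dir, "assignments.csv"))
  write_csv_quiet(result$population_summary$summaries,
                  file.path(out_dir, "population_summaries.csv"))
  write_csv_quiet(result$population_summary$counts,
                  file.path(out_dir, "population_group_counts.csv"))
  write_csv_quiet(result$intersections,
                  file.path(out_dir, "intersections.csv"))
  write_csv_quiet(result$habitat, file.path(out_dir, "habitat.csv"))
  yaml::write_yaml(result$report, file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}
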