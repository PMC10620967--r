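# Population-level cytotype structure: per-population summaries, upset-style
# group-combination counts and habitat association diagnostics.

#' Summarise cytotype composition per population
#'
#' One summary row per population: the set of delimited groups present
#' (UNASSIGNED individuals are excluded from `groups_present` and reported
#' separately, so "mixed" is strictly about delimited groups), a mixed flag
#' (two or more groups present), and habitat. Populations whose assigned
#' individuals were all filtered out are flagged through `n_assigned = 0`,
#' never dropped.
#'
#' @param assignments Data.frame from [assign_groups()], with
#'   `population_id` present.
#' @param populations Data.frame with `population_id` and `habitat`.
#' @return A list of class `population_summary` with
#'   \describe{
#'     \item{summaries}{data.frame `population_id`, `habitat`, `n_assigned`,
#'       `n_unassigned`, `n_groups`, `is_mixed`, `combination` (group labels
#'       joined with `+`, ordered)}
#'     \item{counts}{long data.frame `population_id`, `group`, `n` of
#'       per-group individual counts (assigned groups only)}
#'   }
#' @export
summarize_populations <- function(assignments, populations) {
  stopifnot(all(c("population_id", "group") %in% names(assignments)),
            all(c("population_id", "habitat") %in% names(populations)))
  unknown <- setdiff(unique(assignments$population_id),
                     populations$population_id)
  if (length(unknown))
    stop("assignments reference unknown population_id(s): ",
         paste(unknown, collapse = ", "))
  bad_hab <- setdiff(unique(populations$habitat),
                     c("natural", "anthropogenic"))
  if (length(bad_hab))
    stop("habitat must be 'natural' or 'anthropogenic'; got: ",
         paste(bad_hab, collapse = ", "))

  pops <- populations$population_id
  rows <- lapply(pops, function(p) {
    a <- assignments[assignments$population_id == p, , drop = FALSE]
    assigned <- a$group[a$group != "UNASSIGNED"]
    present <- sort(unique(assigned))
    data.frame(
      population_id = p,
      habitat = populations$habitat[populations$population_id == p][1],
      n_assigned = length(assigned),
      n_unassigned = sum(a$group == "UNASSIGNED"),
      n_groups = length(present),
      is_mixed = length(present) >= 2,
      combination = paste(present, collapse = "+"),
      stringsAsFactors = FALSE
    )
  })
  summaries <- do.call(rbind, rows)

  assigned <- assignments[assignments$group != "UNASSIGNED", , drop = FALSE]
  counts <- as.data.frame(table(population_id = assigned$population_id,
                                group = assigned$group),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  counts <- counts[counts$n > 0, , drop = FALSE]
  counts <- counts[order(counts$population_id, counts$group), , drop = FALSE]
  rownames(counts) <- NULL

  structure(list(summaries = summaries, counts = counts),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  s <- x$summaries
  cat("<population_summary> ", nrow(s), " populations, ",
      sum(s$is_mixed), " mixed (",
      round(100 * mean(s$is_mixed), 1), "%), ",
      sum(s$habitat == "anthropogenic"), " anthropogenic\n", sep = "")
  invisible(x)
}

#' Upset-style group-combination counts
#'
#' Tabulates how many populations carry each observed combination of
#' genome-size groups, split by habitat — the tabular equivalent of an upset
#' intersection plot. Combinations are ordered by frequency descending, ties
#' broken by lexicographic combination label.
#'
#' @param summary A `population_summary` (or its `summaries` data.frame).
#' @return Data.frame `combination`, `n_populations`, `n_natural`,
#'   `n_anthropogenic`.
#' @export
intersection_counts <- function(summary) {
  s <- if (inherits(summary, "population_summary")) summary$summaries
       else summary
  if (!nrow(s)) stop("need at least one population summary")
  combos <- split(s, s$combination)
  out <- do.call(rbind, lapply(combos, function(g) data.frame(
    combination = g$combination[1],
    n_populations = nrow(g),
    n_natural = sum(g$habitat == "natural"),
    n_anthropogenic = sum(g$habitat == "anthropogenic"),
    stringsAsFactors = FALSE
  )))
  out <- out[order(-out$n_populations, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-by-habitat association with a permutation diagnostic
#'
#' For each genome-size group, counts the natural and anthropogenic
#' populations containing it, and attaches a two-sided permutation p-value
#' for association between group presence and habitat: habitat labels are
#' shuffled across populations (seeded) and the anthropogenic presence count
#' is re-tabulated. The contingency counts are the descriptive result; the
#' p-values are diagnostics beyond the descriptive summary — with few
#' populations the discrete permutation distribution makes them
#' conservative.
#'
#' @param summary A `population_summary`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return Data.frame `group`, `n_natural`, `n_anthropogenic`,
#'   `n_populations`, `p_value`; `p_value` is `NA` (with a notice) when all
#'   populations share one habitat class.
#' @export
habitat_association <- function(summary, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(summary, "population_summary"))
  s <- summary$summaries
  if (nrow(s) < 2) stop("need at least 2 populations")
  groups <- sort(unique(summary$counts$group))
  if (!length(groups)) stop("no assigned groups to tabulate")
  # presence matrix: population x group
  pres <- vapply(groups, function(g)
    s$population_id %in%
      summary$counts$population_id[summary$counts$group == g],
    logical(nrow(s)))
  if (nrow(s) == 1) pres <- matrix(pres, nrow = 1)
  anthro <- s$habitat == "anthropogenic"
  obs <- colSums(pres & anthro)

  out <- data.frame(group = groups,
                    n_natural = colSums(pres & !anthro),
                    n_anthropogenic = obs,
                    n_populations = colSums(pres),
                    p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(unique(s$habitat)) < 2) {
    message("all populations share one habitat class; ",
            "association test skipped")
    return(out)
  }
  with_seed(seed, {
    n_pop <- nrow(s)
    perm_stats <- matrix(0L, n_perm, length(groups))
    for (b in seq_len(n_perm)) {
      perm_anthro <- anthro[sample.int(n_pop)]
      perm_stats[b, ] <- colSums(pres & perm_anthro)
    }
    for (g in seq_along(groups)) {
      null_mean <- mean(perm_stats[, g])
      dev_obs <- abs(obs[g] - null_mean)
      # add-one estimator: includes the observed configuration
      out$p_value[g] <-
        (1 + sum(abs(perm_stats[, g] - null_mean) >= dev_obs - 1e-12)) /
        (n_perm + 1)
    }
  })
  out
}
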