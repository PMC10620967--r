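# Genome-size group delimitation: chromosome-count anchoring of mixture
# components, overlap tests, interval construction and individual assignment.

#' Ploidy level from a somatic chromosome count
#'
#' For a complex with monoploid number x = 7, ploidy is `2n / 7`. Counts not
#' divisible by 7 indicate a putative aneuploid and are rejected — aneuploids
#' cannot be placed in a euploid group series and must be handled by hand.
#'
#' @param two_n Somatic chromosome count(s), 2n.
#' @param x Monoploid chromosome number (default 7).
#' @return Integer ploidy level(s).
#' @examples
#' ploidy_from_count(c(14, 28, 35, 42, 49))
#' @export
ploidy_from_count <- function(two_n, x = 7) {
  if (any(two_n <= 0)) stop("chromosome counts must be positive")
  off <- two_n %% x != 0
  if (any(off))
    stop("putative aneuploid count(s) not divisible by x = ", x, ": ",
         paste(two_n[off], collapse = ", "),
         " — verify the count before use")
  as.integer(two_n / x)
}

#' Map mixture components to ploidy via chromosome-counted anchors
#'
#' Classifies each anchor's genome size under the fitted mixture
#' (max-posterior) and requires every component to contain at least one
#' anchor. Each component's ploidy is the majority ploidy of its anchors:
#' at realistic group overlaps an anchor lying in the boundary region is
#' occasionally captured by the neighbouring component, so disagreeing
#' minority anchors are surfaced with a warning rather than treated as
#' fatal; an exact tie (no majority) remains an error, since the
#' component's ploidy is then genuinely undetermined. Components sharing a
#' ploidy level receive letter suffixes A, B, C... by ascending mean (e.g.
#' `6xA < 6xB < 6xC`); a ploidy with a single component gets no suffix.
#'
#' @param model A fitted `fc_gmm`.
#' @param anchors Data.frame with columns `sample_id`, `gs` (measured genome
#'   size, pg) and `two_n` (chromosome count).
#' @param x Monoploid number passed to [ploidy_from_count()].
#' @return Data.frame `component`, `ploidy`, `label`, `n_anchors`,
#'   `n_conflicting` (minority anchors), ordered by component (ascending
#'   mean).
#' @export
map_components_to_ploidy <- function(model, anchors, x = 7) {
  stopifnot(inherits(model, "fc_gmm"))
  need <- c("sample_id", "gs", "two_n")
  if (!all(need %in% names(anchors)))
    stop("anchors must have columns: ", paste(need, collapse = ", "))
  if (!nrow(anchors)) stop("no anchors supplied")
  ploidy <- ploidy_from_count(anchors$two_n, x)
  comp <- classify(model, anchors$gs)$labels

  uncovered <- setdiff(seq_len(model$k), unique(comp))
  if (length(uncovered))
    stop("component(s) without any chromosome-counted anchor: ",
         paste(uncovered, collapse = ", "),
         " (means ", paste(round(model$means[uncovered], 3), collapse = ", "),
         " pg); count chromosomes for individuals in these groups")

  comp_ploidy <- integer(model$k)
  n_conflicting <- integer(model$k)
  for (j in seq_len(model$k)) {
    tab <- table(ploidy[comp == j])
    top <- tab[tab == max(tab)]
    if (length(top) > 1)
      stop("anchors tie on ploidy within component ", j,
           " (mean ", round(model$means[j], 3), " pg): 2n = ",
           paste(sort(unique(anchors$two_n[comp == j])), collapse = ", "),
           " — ploidy undetermined, count more chromosomes")
    comp_ploidy[j] <- as.integer(names(top))
    n_conflicting[j] <- sum(tab) - max(tab)
    if (n_conflicting[j] > 0)
      warning(n_conflicting[j], " anchor(s) in component ", j,
              " (mean ", round(model$means[j], 3),
              " pg) disagree with its majority ploidy ", comp_ploidy[j],
              "; boundary individuals captured by a neighbouring ",
              "component — inspect them", call. = FALSE)
  }

  label <- character(model$k)
  for (p in unique(comp_ploidy)) {
    idx <- which(comp_ploidy == p) # already ascending in mean
    if (length(idx) == 1) {
      label[idx] <- paste0(p, "x")
    } else {
      label[idx] <- paste0(p, "x", LETTERS[seq_along(idx)])
    }
  }
  data.frame(component = seq_len(model$k), ploidy = comp_ploidy,
             label = label,
             n_anchors = as.integer(tabulate(comp, model$k)),
             n_conflicting = n_conflicting,
             stringsAsFactors = FALSE)
}

#' Do two Gaussian components overlap at given percentiles?
#'
#' Components overlap when their central percentile intervals (1st to 99th
#' by default) intersect. Percentiles of `Normal(mu, sigma)` are computed in
#' closed form as `mu + z_p * sigma`.
#'
#' @param mean_a,sd_a,mean_b,sd_b Component parameters, pg.
#' @param containment Two percentiles defining each interval.
#' @return Logical flag.
#' @examples
#' component_overlap(2.587, 0.036, 5.265, 0.147)  # FALSE: far apart
#' component_overlap(7.752, 0.101, 8.196, 0.132)  # TRUE: intervals intersect
#' @export
component_overlap <- function(mean_a, sd_a, mean_b, sd_b,
                              containment = c(0.01, 0.99)) {
  lo_a <- stats::qnorm(containment[1], mean_a, sd_a)
  hi_a <- stats::qnorm(containment[2], mean_a, sd_a)
  lo_b <- stats::qnorm(containment[1], mean_b, sd_b)
  hi_b <- stats::qnorm(containment[2], mean_b, sd_b)
  lo_a <= hi_b && lo_b <= hi_a
}

#' Delimit genome-size groups from a mixture and its anchors
#'
#' Builds one genome-size interval per mixture component. Each group starts
#' from its component's central percentile interval (criterion: 1st and 99th
#' percentiles of the fitted Gauss curve). For each adjacent pair of groups
#' of *different* ploidy whose components overlap, the boundary is instead
#' set by the chromosome-counted individuals: the lower group's high edge
#' becomes the largest anchored genome size of the lower ploidy and the
#' upper group's low edge the smallest anchored genome size of the upper
#' ploidy. Adjacent groups of the *same* ploidy keep their percentile edges
#' (their overlap zone later yields unassigned individuals). The outermost
#' edges are unbounded by default — boundaries are only defined between
#' groups — or percentile-bounded with `bounded_tails = TRUE`.
#'
#' Intervals are half-open `[low, high)`, except that an anchor-derived high
#' edge is inclusive: the boundary anchor individual itself belongs to its
#' own group.
#'
#' @param model A fitted `fc_gmm`.
#' @param mapping Component-to-ploidy mapping from
#'   [map_components_to_ploidy()].
#' @param anchors Data.frame `sample_id`, `gs`, `two_n` (same as used for
#'   the mapping).
#' @param containment Percentile pair for provisional edges and the overlap
#'   test.
#' @param bounded_tails Bound the outermost edges at their percentiles
#'   instead of leaving them unbounded.
#' @param x Monoploid number.
#' @return Data.frame of groups ordered by component mean: `label`,
#'   `ploidy`, `component`, `low`, `high`, `low_rule`, `high_rule` (each
#'   rule one of `"anchor"`, `"percentile"`, `"unbounded"`).
#' @export
delimit_groups <- function(model, mapping, anchors,
                           containment = c(0.01, 0.99),
                           bounded_tails = FALSE, x = 7) {
  stopifnot(inherits(model, "fc_gmm"))
  k <- model$k
  if (nrow(mapping) != k) stop("mapping must cover every component")
  ploidy <- mapping$ploidy
  anchor_ploidy <- ploidy_from_count(anchors$two_n, x)

  low <- stats::qnorm(containment[1], model$means, model$sds)
  high <- stats::qnorm(containment[2], model$means, model$sds)
  low_rule <- rep("percentile", k)
  high_rule <- rep("percentile", k)

  if (k > 1) {
    for (j in seq_len(k - 1)) {
      ov <- component_overlap(model$means[j], model$sds[j],
                              model$means[j + 1], model$sds[j + 1],
                              containment)
      if (ov && ploidy[j] != ploidy[j + 1]) {
        lo_anchors <- anchors$gs[anchor_ploidy == ploidy[j]]
        hi_anchors <- anchors$gs[anchor_ploidy == ploidy[j + 1]]
        if (!length(lo_anchors) || !length(hi_anchors))
          stop("no anchors of ploidy ", ploidy[j], "/", ploidy[j + 1],
               " available to delimit overlapping heteroploid groups ",
               mapping$label[j], "/", mapping$label[j + 1])
        high[j] <- max(lo_anchors)
        low[j + 1] <- min(hi_anchors)
        high_rule[j] <- "anchor"
        low_rule[j + 1] <- "anchor"
      }
      # same-ploidy overlap: percentile edges stand
    }
  }
  if (!bounded_tails) {
    low[1] <- -Inf; low_rule[1] <- "unbounded"
    high[k] <- Inf; high_rule[k] <- "unbounded"
  }
  bad <- which(low >= high)
  if (length(bad))
    stop("anchor rule produced an empty interval for group(s) ",
         paste(mapping$label[bad], collapse = ", "),
         " (low >= high): pathological anchor placement — inspect the ",
         "anchored genome sizes near these boundaries")
  data.frame(label = mapping$label, ploidy = ploidy,
             component = mapping$component,
             low = low, high = high,
             low_rule = low_rule, high_rule = high_rule,
             stringsAsFactors = FALSE)
}

# interval membership respecting the anchor-inclusive upper edge
in_group <- function(gs, group) {
  gs >= group$low &
    (gs < group$high | (group$high_rule == "anchor" & gs == group$high))
}

#' Assign individuals to delimited genome-size groups
#'
#' A sample is assigned to a group iff its genome size lies in exactly one
#' group interval. Samples in no interval, or in the overlap zone of two
#' intervals (homoploid neighbours), are left `UNASSIGNED` with a rationale.
#' Chromosome-counted samples whose assigned group contradicts their counted
#' ploidy are reported via the `conflict` column — surfaced, never dropped.
#'
#' @param measurements Data.frame with `sample_id` and `genome_size`
#'   (QC-passed measurements).
#' @param groups Groups table from [delimit_groups()].
#' @param anchors Optional data.frame `sample_id`, `two_n` used to flag
#'   anchor conflicts.
#' @param x Monoploid number.
#' @return Data.frame `sample_id`, `genome_size`, `group` (label or
#'   `"UNASSIGNED"`), `rationale`, `conflict` (logical), one row per input
#'   measurement, plus any extra input columns (e.g. `population_id`)
#'   carried through.
#' @export
assign_groups <- function(measurements, groups, anchors = NULL, x = 7) {
  stopifnot(all(c("sample_id", "genome_size") %in% names(measurements)))
  gs <- measurements$genome_size
  n <- length(gs)
  member <- vapply(seq_len(nrow(groups)), function(j)
    in_group(gs, groups[j, ]), logical(n))
  if (n == 1) member <- matrix(member, nrow = 1)
  hits <- rowSums(member)
  group <- rep("UNASSIGNED", n)
  rationale <- character(n)
  one <- hits == 1
  group[one] <- groups$label[max.col(member, ties.method = "first")[one]]
  rationale[one] <- "inside exactly one group interval"
  rationale[hits == 0] <- "outside every group interval"
  rationale[hits >= 2] <- "ambiguous: inside overlapping group intervals"

  out <- measurements
  out$group <- group
  out$rationale <- rationale
  out$conflict <- FALSE
  if (!is.null(anchors) && nrow(anchors)) {
    idx <- match(out$sample_id, anchors$sample_id)
    counted <- !is.na(idx)
    anchor_ploidy <- ploidy_from_count(anchors$two_n[idx[counted]], x)
    assigned_ploidy <- groups$ploidy[match(out$group[counted], groups$label)]
    conf <- is.na(assigned_ploidy) | assigned_ploidy != anchor_ploidy
    out$conflict[counted] <- conf
    if (any(conf))
      warning(sum(conf), " chromosome-counted individual(s) not assigned ",
              "to the group of their counted ploidy: ",
              paste(utils::head(out$sample_id[counted][conf], 5),
                    collapse = ", "),
              if (sum(conf) > 5) ", ...", call. = FALSE)
  }
  out
}
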