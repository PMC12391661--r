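# Simulated 2D SEM sections of 3D pore models: volume-normalized subsampling,
# flattening along z, re-hulling, resolution filtering and distribution
# comparison against cross-sectional (SEM-derived) diameters.

#' Sampling policy for simulated SEM sections
#'
#' @param volume_budget Total pore volume per sample, um^3 (default 3e5): the
#'   random selection stops just before the pore that would push the running
#'   total past the budget.
#' @param min_diameter Resolution floor on the flattened diameter, um. No
#'   default: in practice it is the smallest diameter resolvable in the
#'   cryo-micrographs being compared against. `NA` disables the rule.
#' @param min_area Minimum flattened pore area, um^2 (default 10, the usual
#'   visual-detection floor for SEM pores).
#' @param seed Integer seed for the random selection.
#' @return List of class `sampling_policy`.
#' @export
sampling_policy <- function(volume_budget = 300000, min_diameter = NA,
                            min_area = 10, seed = 1L) {
  assert_positive(volume_budget, "volume_budget")
  if (!is.na(min_diameter)) assert_nonnegative(min_diameter, "min_diameter")
  assert_nonnegative(min_area, "min_area")
  structure(list(volume_budget = volume_budget, min_diameter = min_diameter,
                 min_area = min_area, seed = as.integer(seed)),
            class = "sampling_policy")
}

#' Random pore selection under a total-volume budget
#'
#' Uniformly random, without replacement: pores are drawn in a seeded random
#' order and accepted while the running total volume stays within the budget;
#' the draw stops at the first pore that would exceed it. This normalizes the
#' sampled gel volume across samples (total selected volume is equal to or a
#' little less than the budget).
#'
#' @param pores List of 3D `pore_model` objects (or a `pore_set`).
#' @param policy A [sampling_policy()].
#' @return List of the selected `pore_model`s, with attribute
#'   `total_volume`.
#' @export
sample_pores_by_volume <- function(pores, policy) {
  if (inherits(pores, "pore_set")) pores <- pores$pores
  if (!length(pores)) {
    return(structure(list(), total_volume = 0))
  }
  vols <- vapply(pores, `[[`, numeric(1), "volume")
  ord <- with_seed(policy$seed, sample.int(length(pores)))
  total <- 0
  take <- integer(0)
  for (i in ord) {
    if (total + vols[i] > policy$volume_budget) break
    total <- total + vols[i]
    take <- c(take, i)
  }
  structure(pores[take], total_volume = total)
}

#' Flatten a 3D pore model to a simulated SEM section
#'
#' Drops the z coordinate of each hull vertex, re-applies the convex hull to
#' the projected xy points, and quantifies the planar model: area, 2D Feret
#' diameter and polygon centroid. Because projection can only contract
#' distances, the flattened diameter never exceeds the 3D one — the mechanism
#' by which cross-sectional 2D imaging underestimates pore size.
#'
#' @param pore A 3D `pore_model`.
#' @return Object of class `flat_pore`: `source_track_id`, `vertices_2d`
#'   (closed CCW ring), `area` (um^2), `diameter_2d` (um), `centroid`.
#' @export
flatten_pore <- function(pore) {
  stopifnot(inherits(pore, "pore_model"))
  if (pore$dims != 3L) {
    ph_stop("flatten_pore() expects a 3D pore model", "porehull_domain_error")
  }
  h <- convex_hull_2d(pore$vertices[, 1:2, drop = FALSE])
  structure(list(source_track_id = pore$track_id,
                 vertices_2d = h$ring,
                 area = h$area,
                 diameter_2d = max_pairwise_distance(
                   h$ring[-nrow(h$ring), , drop = FALSE]),
                 centroid = h$centroid),
            class = "flat_pore")
}

#' @export
print.flat_pore <- function(x, ...) {
  cat(sprintf("<flat_pore> track %s: area %.4g um^2, diameter %.4g um\n",
              x$source_track_id, x$area, x$diameter_2d))
  invisible(x)
}

#' Resolution filter for flattened pores
#'
#' Mirrors the resolution difference between fluorescence tracking and
#' cryo-micrographs: removes flattened pores whose diameter falls below
#' `policy$min_diameter` or whose area falls below `policy$min_area`.
#' Idempotent.
#'
#' @param flats List of `flat_pore` objects.
#' @param policy A [sampling_policy()].
#' @return Filtered list with attribute `removed`, a named count per rule.
#' @export
apply_resolution_filter <- function(flats, policy) {
  if (!length(flats)) {
    return(structure(list(), removed = c(diameter = 0L, area = 0L)))
  }
  dia <- vapply(flats, `[[`, numeric(1), "diameter_2d")
  area <- vapply(flats, `[[`, numeric(1), "area")
  drop_d <- if (is.na(policy$min_diameter)) rep(FALSE, length(flats)) else
    dia < policy$min_diameter
  drop_a <- area < policy$min_area
  keep <- !(drop_d | drop_a)
  structure(flats[keep],
            removed = c(diameter = sum(drop_d), area = sum(drop_a)))
}

#' Compare two pore-diameter distributions
#'
#' Two-sided Mann-Whitney U test (via [stats::wilcox.test()]; R's W statistic
#' for the first sample is the U statistic) between two diameter samples,
#' e.g. simulated-SEM versus empirical SEM diameters. When several pairs are
#' tested, apply Bonferroni correction to the returned p-values with
#' `stats::p.adjust(p, "bonferroni")`.
#'
#' @param a,b Numeric vectors of diameters (um), each non-empty.
#' @return List with `statistic` (U for sample `a`), `p_value`, `median_a`,
#'   `median_b`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(a, b) {
  if (!length(a) || !length(b)) {
    ph_stop("both samples must be non-empty", "porehull_validation_error")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                       correct = FALSE)
  )
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       median_a = stats::median(a),
       median_b = stats::median(b),
       n_a = length(a), n_b = length(b))
}
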