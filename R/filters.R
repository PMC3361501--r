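#' Specify a candidate neighborhood filter
#'
#' A filter is a candidate neighborhood definition applied around each point
#' of residence in turn: either a fixed geographic radius, or a target
#' head-count of individuals accumulated from the nearest points.
#'
#' @param kind one of `"geographic"` (fixed radius), `"nearly_fixed_population"`
#'   (accumulate whole points until the head-count first reaches the target;
#'   may overshoot) or `"fixed_population"` (as before, but the last captured
#'   point contributes fractionally so the head-count matches the target
#'   exactly).  `"population"` is accepted as an alias for
#'   `"nearly_fixed_population"`, the population scheme evaluated in practice.
#' @param size radius in meters (geographic) or target persons (population
#'   kinds); must be > 0.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind, size) {
  kind <- match.arg(kind, c("geographic", "nearly_fixed_population",
                            "fixed_population", "population"))
  if (kind == "population") kind <- "nearly_fixed_population"
  size <- as.numeric(size)
  if (length(size) != 1L || !is.finite(size) || size <= 0) {
    stop("filter size must be a single positive number")
  }
  structure(list(kind = kind, size = size), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  unit <- if (x$kind == "geographic") "m" else "persons"
  cat(sprintf("filter_spec: %s, size %g %s\n", x$kind, x$size, unit))
  invisible(x)
}

filter_unit <- function(kind) if (kind == "geographic") "m" else "persons"

# Assemble a filter_capture from a center profile and the index m of the last
# captured position along the neighbor ordering.  w is the weight of the last
# captured (training) point; reason flags a capture the LOOCV must exclude.
build_capture <- function(ps, ci, prof, spec, m, w = 1, reason = NA_character_) {
  pop <- ps$population; pos <- ps$positives
  tr_idx <- if (m >= 2L) prof$idx[2:m] else integer(0)
  wts <- rep(1, length(tr_idx))
  if (length(wts) > 0) wts[length(wts)] <- w
  tr_pop <- if (m >= 2L) (prof$cpop[m - 1L] - pop[ci]) + w * pop[prof$idx[m]] else 0
  tr_pos <- if (m >= 2L) (prof$cpos[m - 1L] - pos[ci]) + w * pos[prof$idx[m]] else 0
  if (is.na(reason) && tr_pop == 0) reason <- "empty_training"
  structure(list(
    center_id = ps$id[ci],
    spec = spec,
    test_population = pop[ci],
    test_positives = pos[ci],
    training_members = data.frame(point_id = ps$id[tr_idx], weight = wts,
                                  stringsAsFactors = FALSE),
    training_population = tr_pop,
    training_positives = tr_pos,
    achieved_radius_m = prof$d[m],
    achieved_population = pop[ci] + tr_pop,
    excluded_reason = reason
  ), class = "filter_capture")
}

#' @export
print.filter_capture <- function(x, ...) {
  cat(sprintf("filter_capture: center %s, %s %g %s\n", x$center_id,
              x$spec$kind, x$spec$size, filter_unit(x$spec$kind)))
  cat(sprintf("  test: %g persons (%g positive); training: %g persons (%g positive) from %d point(s)\n",
              x$test_population, x$test_positives, x$training_population,
              x$training_positives, nrow(x$training_members)))
  cat(sprintf("  achieved radius %g m, achieved population %g\n",
              x$achieved_radius_m, x$achieved_population))
  if (!is.na(x$excluded_reason)) cat("  flagged:", x$excluded_reason, "\n")
  invisible(x)
}

#' Resolve one neighborhood capture for one center point
#'
#' Splits the study population, for a single center point and a single
#' candidate filter, into the test set (the individuals living at the center
#' point) and the training set (the remaining individuals captured by the
#' filter).  The three kinds are:
#'
#' * `geographic_filter()`: captures every point within the closed ball of
#'   the given radius around the center.
#' * `nearly_fixed_population_filter()`: walks the nearest-neighbor ordering
#'   from the center, accumulating whole points until the cumulative
#'   head-count first reaches the target; the capture may overshoot the
#'   target if the last point brings more individuals than needed.
#' * `fixed_population_filter()`: same walk, but the last captured point
#'   contributes only the fraction of its individuals needed to hit the
#'   target exactly (expected-value apportionment of its positives; the
#'   center/test point is never fractionated).
#'
#' A capture whose training set is empty (isolated point under a small
#' radius, or a center that alone meets a population target) is returned
#' flagged `empty_training`, not errored; [loocv_mse()] excludes it.  A
#' population target that exhausts the whole point set is flagged
#' `target_unreached` (an error for the fixed-population kind, whose
#' precondition is `target <= total_population`).
#'
#' @param ps a `point_set`.
#' @param center_id id of the center point.
#' @param radius geographic radius in meters (> 0).
#' @param target target head-count in persons (> 0).
#' @param target_includes_center logical; if `TRUE` (default) the center
#'   point's own individuals count toward the population target, if `FALSE`
#'   only training individuals are accumulated until the target is met.
#' @return A `filter_capture` with the test/training populations and
#'   positives, the training members and weights, the achieved radius
#'   (distance to the farthest captured point) and achieved population.
#' @examples
#' f1 <- make_fixture("F1")
#' geographic_filter(f1, "A", radius = 15)
#' @export
geographic_filter <- function(ps, center_id, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  ci <- ps_index(ps, center_id)
  prof <- center_profile(ps, ci)
  m <- findInterval(radius, prof$d)  # count of distances <= radius
  build_capture(ps, ci, prof, filter_spec("geographic", radius), m)
}

#' @rdname geographic_filter
#' @export
nearly_fixed_population_filter <- function(ps, center_id, target,
                                           target_includes_center = TRUE) {
  if (!is.finite(target) || target <= 0) stop("target must be > 0")
  ci <- ps_index(ps, center_id)
  prof <- center_profile(ps, ci)
  thr <- if (target_includes_center) prof$cpop else prof$cpop - ps$population[ci]
  m <- findInterval(target, thr, left.open = TRUE) + 1L  # first prefix >= target
  reason <- NA_character_
  if (m > nrow(ps)) {
    m <- nrow(ps)
    reason <- "target_unreached"
  }
  build_capture(ps, ci, prof, filter_spec("nearly_fixed_population", target), m,
                reason = reason)
}

#' @rdname geographic_filter
#' @export
fixed_population_filter <- function(ps, center_id, target,
                                    target_includes_center = TRUE) {
  if (!is.finite(target) || target <= 0) stop("target must be > 0")
  if (target > total_population(ps)) {
    stop("fixed-population target exceeds the total population")
  }
  ci <- ps_index(ps, center_id)
  prof <- center_profile(ps, ci)
  thr <- if (target_includes_center) prof$cpop else prof$cpop - ps$population[ci]
  m <- findInterval(target, thr, left.open = TRUE) + 1L
  spec <- filter_spec("fixed_population", target)
  if (m > nrow(ps)) {
    # Reachable only when the target excludes the center's own individuals.
    return(build_capture(ps, ci, prof, spec, nrow(ps),
                         reason = "target_unreached"))
  }
  if (m == 1L) {
    # Center alone meets the target; the test point is never fractionated.
    return(build_capture(ps, ci, prof, spec, 1L))
  }
  before <- thr[m - 1L]
  w <- (target - before) / ps$population[prof$idx[m]]
  build_capture(ps, ci, prof, spec, m, w = w)
}

#' @rdname geographic_filter
#' @param spec a `filter_spec`; dispatches to the matching filter above.
#' @export
apply_filter <- function(ps, spec, center_id, target_includes_center = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$kind,
    geographic = geographic_filter(ps, center_id, spec$size),
    nearly_fixed_population =
      nearly_fixed_population_filter(ps, center_id, spec$size,
                                     target_includes_center),
    fixed_population =
      fixed_population_filter(ps, center_id, spec$size,
                              target_includes_center))
}
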