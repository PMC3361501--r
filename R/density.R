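# Captured population within closed balls of each radius around each point
# (center included).  Dense path: full distance vector per center.  Binned
# path: points are bucketed into square cells of side max(radii) so each
# center only scans its 3x3 cell neighborhood; results are identical because
# any point within max(radii) of a center lies in that neighborhood.
capture_matrix <- function(ps, radii, method = c("auto", "dense", "binned")) {
  method <- match.arg(method)
  n <- nrow(ps)
  if (method == "auto") method <- if (n > 2000L) "binned" else "dense"
  radii <- as.numeric(radii)
  out <- matrix(NA_real_, n, length(radii))
  pop <- ps$population
  scan <- function(centers, cand) {
    for (i in centers) {
      d <- sqrt((ps$x[cand] - ps$x[i])^2 + (ps$y[cand] - ps$y[i])^2)
      o <- order(d)
      cp <- cumsum(pop[cand][o])
      out[i, ] <<- cp[findInterval(radii, d[o])]
    }
  }
  if (method == "dense") {
    scan(seq_len(n), seq_len(n))
  } else {
    w <- max(radii)
    cx <- floor(ps$x / w); cy <- floor(ps$y / w)
    cells <- split(seq_len(n), paste(cx, cy))
    key <- function(a, b) paste(a, b)
    for (cell in cells) {
      a <- cx[cell[1L]]; b <- cy[cell[1L]]
      nb <- as.vector(outer(a + (-1:1), b + (-1:1), key))
      cand <- unlist(cells[intersect(nb, names(cells))], use.names = FALSE)
      scan(cell, cand)
    }
  }
  out
}

#' Local population density around each point
#'
#' The density seen from a point of residence: the individuals living within
#' the closed ball of the given radius (the center's own included), divided
#' by the ball area `pi * radius^2`, expressed in persons per hectare
#' (10,000 m2).  No edge correction is applied near the study-area boundary,
#' so densities at border points are biased downward (their balls extend over
#' empty space).
#'
#' @param ps a `point_set`.
#' @param radius ball radius in meters (> 0).
#' @param center_id optional single id; if given, return that point's density
#'   only.
#' @return Numeric vector of densities (persons/ha), one per point (named by
#'   id), or a single value when `center_id` is given.
#' @examples
#' f1 <- make_fixture("F1")
#' local_density(f1, radius = 15, center_id = "A")  # 6 persons in a 15 m ball
#' @export
local_density <- function(ps, radius, center_id = NULL) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  capt <- capture_matrix(ps, radius)[, 1L]
  dens <- capt / (pi * radius^2) * 1e4
  names(dens) <- ps$id
  if (!is.null(center_id)) dens[[ps_index(ps, center_id)]] else dens
}

#' Coefficient of variation of local population density
#'
#' Evaluates [local_density()] at every point as center and returns the
#' coefficient of variation (standard deviation over mean) across points.
#' By default the population standard deviation (divisor n) is used: the
#' point set is treated as the full census of the study area, not a sample.
#'
#' @param ps a `point_set` with at least 2 points.
#' @param radius ball radius in meters (> 0).
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @return The CV (dimensionless, >= 0).
#' @export
density_cv <- function(ps, radius, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(ps) < 2L) stop("CV needs at least 2 points")
  cv_from_capture(capture_matrix(ps, radius)[, 1L], sd_type)
}

cv_from_capture <- function(capt, sd_type) {
  # densities are capt / (pi r^2) * 1e4; the constant cancels in sd/mean
  mu <- mean(capt)
  v <- mean((capt - mu)^2)
  if (sd_type == "sample") v <- v * length(capt) / (length(capt) - 1)
  sqrt(v) / mu
}

#' Density-CV profile over a radius grid and heterogeneity class
#'
#' Computes the CV of local population density at each radius of the grid
#' (default 10--200 m by 10 m), summarizes the profile by its mean and
#' standard deviation, and classifies the spatial distribution of the
#' population from the mean CV via [classify_spatial_distribution()].
#'
#' @param ps a `point_set` with at least 2 points.
#' @param radii strictly increasing vector of radii in meters.
#' @param sd_type CV convention, see [density_cv()].
#' @param method distance-scan strategy (`"auto"` picks cell binning for
#'   large point sets); the two paths give identical results.
#' @return An object of class `density_profile`: list with `radius_grid`,
#'   `cv_per_radius`, `mean_cv`, `std_cv` (sample sd over the grid) and
#'   `classification`.
#' @examples
#' s2 <- make_fixture("S2", seed = 1)
#' cv_profile(s2)$classification  # "homogeneous"
#' @export
cv_profile <- function(ps, radii = seq(10, 200, by = 10),
                       sd_type = c("population", "sample"),
                       method = c("auto", "dense", "binned")) {
  sd_type <- match.arg(sd_type)
  if (nrow(ps) < 2L) stop("CV needs at least 2 points")
  radii <- as.numeric(radii)
  if (length(radii) == 0L || any(!is.finite(radii) | radii <= 0)) {
    stop("radii must be positive")
  }
  if (is.unsorted(radii, strictly = TRUE)) {
    stop("radii must be strictly increasing")
  }
  capt <- capture_matrix(ps, radii, method = match.arg(method))
  cvs <- apply(capt, 2L, cv_from_capture, sd_type = sd_type)
  mean_cv <- mean(cvs)
  std_cv <- if (length(cvs) > 1L) stats::sd(cvs) else 0
  structure(list(radius_grid = radii, cv_per_radius = cvs,
                 mean_cv = mean_cv, std_cv = std_cv,
                 classification = classify_spatial_distribution(mean_cv)),
            class = "density_profile")
}

#' Classify the spatial distribution of a population from its mean density CV
#'
#' Fixed cut-offs on the mean coefficient of variation of local population
#' density: below 0.5 the distribution is homogeneous, from 0.5 up to (but
#' excluding) 0.7 moderately homogeneous, and from 0.7 upward heterogeneous.
#' The boundary values 0.5 and 0.7 fall in the upper class, so the intervals
#' are [0, 0.5), [0.5, 0.7), [0.7, Inf).
#'
#' @param mean_cv mean CV, >= 0.
#' @return One of `"homogeneous"`, `"moderately_homogeneous"`,
#'   `"heterogeneous"`.
#' @examples
#' classify_spatial_distribution(0.36)  # homogeneous
#' classify_spatial_distribution(0.73)  # heterogeneous
#' @export
classify_spatial_distribution <- function(mean_cv) {
  if (!is.finite(mean_cv) || mean_cv < 0) stop("mean_cv must be >= 0")
  if (mean_cv < 0.5) "homogeneous"
  else if (mean_cv < 0.7) "moderately_homogeneous"
  else "heterogeneous"
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d radii (%g-%g m)\n",
              length(x$radius_grid), min(x$radius_grid), max(x$radius_grid)))
  cat(sprintf("  mean CV %.4f (sd %.4f) -> %s\n", x$mean_cv, x$std_cv,
              x$classification))
  invisible(x)
}

#' Plot a density-CV profile
#'
#' CV of local population density against radius, with the homogeneity
#' cut-offs at 0.5 and 0.7 drawn as reference lines.
#'
#' @param x a `density_profile`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$radius_grid, x$cv_per_radius, type = "b", pch = 16,
                 xlab = "radius (m)", ylab = "CV of population density",
                 ylim = range(0, x$cv_per_radius, 0.75), ...)
  graphics::abline(h = c(0.5, 0.7), lty = 3, col = "grey40")
  graphics::mtext(sprintf("mean CV %.3f: %s", x$mean_cv, x$classification),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}
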