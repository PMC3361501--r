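#' Construct a set of geographic points of residence
#'
#' A `point_set` is the basic data container of the package: one row per
#' mapped dwelling location, holding planar coordinates in meters (the caller
#' projects, e.g. UTM; no geodesic math is done), the count of eligible
#' individuals living at the point, and the count of outcome-positive
#' individuals (e.g. vaccinated).
#'
#' @param id character vector of unique, opaque point identifiers.
#' @param x,y numeric planar coordinates in meters (easting/northing).
#' @param population integer counts of eligible individuals, all >= 1.
#' @param positives integer counts of outcome-positive individuals,
#'   `0 <= positives <= population`.
#' @return A data frame of class `point_set` with columns
#'   `id, x, y, population, positives`.
#' @examples
#' ps <- point_set(c("A", "B"), x = c(0, 10), y = c(0, 0),
#'                 population = c(2, 4), positives = c(1, 4))
#' total_population(ps)
#' @export
point_set <- function(id, x, y, population, positives) {
  df <- data.frame(id = as.character(id), x = as.numeric(x), y = as.numeric(y),
                   population = as.numeric(population),
                   positives = as.numeric(positives),
                   stringsAsFactors = FALSE)
  validate_point_set(df)
}

#' Coerce a data frame to a point_set
#'
#' @param df data frame with columns `id, x, y, population, positives`.
#' @return A validated `point_set`.
#' @export
as_point_set <- function(df) {
  req <- c("id", "x", "y", "population", "positives")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  point_set(df$id, df$x, df$y, df$population, df$positives)
}

validate_point_set <- function(df) {
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s at row(s): %s", what,
                   paste(utils::head(which(!ok), 5L), collapse = ", ")))
    }
  }
  bad_row(!is.na(df$id) & nzchar(df$id), "empty or missing id")
  if (anyDuplicated(df$id)) {
    dup <- which(duplicated(df$id))
    stop("duplicate id at row(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad_row(is.finite(df$x) & is.finite(df$y), "non-finite coordinate")
  bad_row(is.finite(df$population) & df$population >= 1,
          "population missing or < 1")
  bad_row(is.finite(df$positives) & df$positives >= 0, "negative positives")
  bad_row(df$positives <= df$population, "positives > population")
  rownames(df) <- NULL
  class(df) <- c("point_set", "data.frame")
  df
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d points, %g eligible individuals, %g positives (%.1f%%)\n",
              nrow(x), total_population(x), total_positives(x),
              100 * total_positives(x) / total_population(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Total eligible individuals / total positives in a point set
#' @param ps a `point_set`.
#' @return A single count.
#' @export
total_population <- function(ps) sum(ps$population)

#' @rdname total_population
#' @export
total_positives <- function(ps) sum(ps$positives)

#' Euclidean distance between two points
#'
#' Coordinates are planar meters; distance is the plain Euclidean norm
#' `sqrt((ax - bx)^2 + (ay - by)^2)`.
#'
#' @param a,b numeric `c(x, y)` vectors, or single-row data frames with
#'   columns `x` and `y` (e.g. rows of a `point_set`).
#' @return Distance in meters.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(a, b) {
  xy <- function(p) {
    if (is.data.frame(p)) p <- c(p$x[1L], p$y[1L])
    p <- as.numeric(p)
    if (length(p) != 2L || !all(is.finite(p))) {
      stop("point must be two finite coordinates")
    }
    p
  }
  a <- xy(a); b <- xy(b)
  sqrt((a[1L] - b[1L])^2 + (a[2L] - b[2L])^2)
}

# Index of an id within a point_set, with a lookup error on miss.
ps_index <- function(ps, id) {
  i <- match(id, ps$id)
  if (is.na(i)) stop("unknown point id: ", id)
  i
}

# Neighbor order for center index ci: center first, then remaining points by
# ascending distance with ties broken by ascending id (C-locale radix sort so
# the order is platform-independent).  Returns integer row indices into ps.
neighbor_order_idx <- function(ps, ci) {
  d <- sqrt((ps$x - ps$x[ci])^2 + (ps$y - ps$y[ci])^2)
  rest <- seq_len(nrow(ps))[-ci]
  c(ci, rest[order(d[rest], ps$id[rest], method = "radix")])
}

#' Rank all points by distance from a center point
#'
#' Produces the full nearest-neighbor ordering used by every filter: the
#' center itself first at distance 0, then every other point by ascending
#' Euclidean distance.  Distance ties are broken by ascending point id
#' (byte order), so the ordering is deterministic; points co-located with the
#' center rank immediately after it.
#'
#' @param ps a `point_set` (n >= 1).
#' @param center_id id of the center point.
#' @return A data frame of class `neighbor_ordering` with columns
#'   `point_id`, `distance_m`, and attribute `center_id`.
#' @export
neighbor_ordering <- function(ps, center_id) {
  ci <- ps_index(ps, center_id)
  ord <- neighbor_order_idx(ps, ci)
  d <- sqrt((ps$x - ps$x[ci])^2 + (ps$y - ps$y[ci])^2)
  out <- data.frame(point_id = ps$id[ord], distance_m = d[ord],
                    stringsAsFactors = FALSE)
  attr(out, "center_id") <- center_id
  class(out) <- c("neighbor_ordering", "data.frame")
  out
}

# Sorted center profile: distances, cumulative populations/positives along the
# neighbor ordering.  The workhorse shared by the filters and the LOOCV sweep.
center_profile <- function(ps, ci) {
  ord <- neighbor_order_idx(ps, ci)
  d <- sqrt((ps$x - ps$x[ci])^2 + (ps$y - ps$y[ci])^2)
  list(idx = ord, d = d[ord],
       cpop = cumsum(ps$population[ord]),
       cpos = cumsum(ps$positives[ord]))
}

#' Read a point set from CSV
#'
#' Expects a UTF-8 CSV with header `id,x,y,population,positives`, decimal
#' points and no thousands separators.  Every validation failure (duplicate
#' id, negative count, positives exceeding population, non-finite coordinate)
#' is reported with the offending row number.
#'
#' @param path path to the CSV file.
#' @return A `point_set`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(id = "character")),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  req <- c("id", "x", "y", "population", "positives")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("x", "y", "population", "positives")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]])
    if (any(bad)) {
      stop(sprintf("non-numeric '%s' at row(s): %s", col,
                   paste(utils::head(which(bad), 5L), collapse = ", ")))
    }
    df[[col]] <- v
  }
  as_point_set(df[req])
}

#' Write a point set to CSV
#'
#' Inverse of [read_points()]; numbers are written with up to 12 significant
#' digits so a write/read round trip is exact for count data and stable for
#' coordinates.
#'
#' @param ps a `point_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(ps, path) {
  df <- as.data.frame(ps)
  for (col in c("x", "y", "population", "positives")) {
    df[[col]] <- fmt_num(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 12-significant-digit decimal rendering shared by all machine-readable output.
fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g", flag = "")
  trimws(out)
}
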