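#' Parse a compact grid specification
#'
#' Grids are written as comma-separated `min:max:step` blocks, e.g.
#' `"50:200:50,400:2000:200"` for the conventional two-regime geographic
#' sweep.  A bare number is a singleton size.
#'
#' @param text grid specification string.
#' @return Strictly increasing numeric vector of sizes.
#' @export
parse_grid <- function(text) {
  blocks <- strsplit(trimws(text), ",", fixed = TRUE)[[1L]]
  sizes <- unlist(lapply(blocks, function(b) {
    parts <- suppressWarnings(as.numeric(strsplit(b, ":", fixed = TRUE)[[1L]]))
    if (anyNA(parts)) stop("cannot parse grid block: ", b)
    if (length(parts) == 1L) parts
    else if (length(parts) == 3L) {
      if (parts[3L] <= 0 || parts[2L] < parts[1L]) {
        stop("grid block must be increasing with a positive step: ", b)
      }
      seq(parts[1L], parts[2L], by = parts[3L])
    } else stop("grid block must be 'size' or 'min:max:step': ", b)
  }))
  if (length(sizes) == 0L || any(sizes <= 0) ||
      is.unsorted(sizes, strictly = TRUE)) {
    stop("grid must be strictly increasing and positive")
  }
  sizes
}

write_table_12sig <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

write_json_12sig <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(12), pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full neighborhood-selection workflow
#'
#' Reads (or accepts) a point set, characterizes the spatial distribution of
#' the population by its density-CV profile, sweeps the candidate filter
#' grid(s) by leave-one-out cross-validation, and writes machine-readable
#' reports: `density.csv` / `density.json`, one `sweep_<kind>.csv` per filter
#' kind, and `optimal.json` holding, per kind, the selected size, its minimum
#' MSE and the achieved-size summary (mean/min/max captured population for
#' the geographic filter, mean/min/max achieved distance for the population
#' filters).  All numbers are serialized with 12 significant digits, so
#' identical input and configuration give byte-identical outputs.
#'
#' @param input path to a points CSV (see [read_points()]) or a `point_set`.
#' @param out_dir output directory (created if needed).
#' @param kinds filter kinds to sweep (see [filter_spec()]; `"population"`
#'   means the nearly-fixed-population scheme).
#' @param geo_sizes,pop_sizes size grids for the geographic and population
#'   sweeps.  Population sizes above the total study population cannot be
#'   reached and are dropped with a message.
#' @param density_radii radius grid for the CV profile.
#' @param target_includes_center see [geographic_filter()].
#' @param dump_captures logical; additionally write `captures_<kind>.csv`
#'   with every per-center LOOCV record at the optimal size.
#' @param plot logical; write MSE-curve and CV-profile plots as SVG.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `points`, `density` (a `density_profile`),
#'   `sweeps` (named list of `mse_curve`), `optima` (named list from
#'   [select_optimal()]), and `files` (paths written).
#' @examples
#' out <- tempfile()
#' res <- run_pipeline(make_fixture("F1"), out, kinds = "geographic",
#'                     geo_sizes = 15, density_radii = c(10, 20), quiet = TRUE)
#' res$optima$geographic$mse  # 29/48
#' @export
run_pipeline <- function(input, out_dir,
                         kinds = c("geographic", "population"),
                         geo_sizes = geographic_grid(),
                         pop_sizes = population_grid(),
                         density_radii = seq(10, 200, by = 10),
                         target_includes_center = TRUE,
                         dump_captures = FALSE,
                         plot = FALSE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  ps <- if (inherits(input, "point_set")) input else read_points(input)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  kinds <- vapply(kinds, function(k) filter_spec(k, 1)$kind, character(1L))
  if (anyDuplicated(kinds)) stop("duplicate filter kinds")
  say("points: n = %d, population = %g, positives = %g", nrow(ps),
      total_population(ps), total_positives(ps))

  files <- character(0)
  prof <- cv_profile(ps, radii = density_radii)
  files <- c(files,
    write_table_12sig(data.frame(radius_m = prof$radius_grid,
                                 cv = prof$cv_per_radius),
                      file.path(out_dir, "density.csv")),
    write_json_12sig(list(mean_cv = prof$mean_cv, std_cv = prof$std_cv,
                          classification = prof$classification),
                     file.path(out_dir, "density.json")))
  say("density: mean CV %.4f (%s)", prof$mean_cv, prof$classification)

  sweeps <- list(); optima <- list()
  for (kind in kinds) {
    sizes <- if (kind == "geographic") geo_sizes else {
      keep <- pop_sizes <= total_population(ps)
      if (!all(keep)) say("dropping %d population size(s) above the total population",
                          sum(!keep))
      pop_sizes[keep]
    }
    if (length(sizes) == 0L) stop("no usable sizes for kind ", kind)
    curve <- withCallingHandlers(
      sweep_filters(ps, kind, sizes, target_includes_center),
      warning = function(w) {
        say("note: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    sweeps[[kind]] <- curve
    files <- c(files, write_table_12sig(
      as.data.frame(curve)[c("kind", "size", "mse", "n_included", "n_excluded",
                             "summary_mean", "summary_min", "summary_max")],
      file.path(out_dir, paste0("sweep_", kind, ".csv"))))
    opt <- select_optimal(curve)
    optima[[kind]] <- opt
    say("%s filter: optimum %g %s, mse %.6g (%d/%d centers included)",
        kind, opt$size, filter_unit(kind), opt$mse,
        opt$entry$n_included, nrow(ps))
    if (dump_captures) {
      recs <- do.call(rbind, lapply(ps$id, function(id) {
        point_error(apply_filter(ps, filter_spec(kind, opt$size), id,
                                 target_includes_center))
      }))
      files <- c(files, write_table_12sig(
        recs, file.path(out_dir, paste0("captures_", kind, ".csv"))))
    }
    if (plot) {
      svg_path <- file.path(out_dir, paste0("mse_", kind, ".svg"))
      grDevices::svg(svg_path); plot(curve); grDevices::dev.off()
      files <- c(files, svg_path)
    }
  }
  if (plot) {
    svg_path <- file.path(out_dir, "density_cv.svg")
    grDevices::svg(svg_path); plot(prof); grDevices::dev.off()
    files <- c(files, svg_path)
  }

  report <- list(
    n_points = nrow(ps),
    total_population = total_population(ps),
    density = list(mean_cv = prof$mean_cv, std_cv = prof$std_cv,
                   classification = prof$classification),
    optimal = lapply(optima, function(o) {
      list(kind = o$kind, size = o$size, mse = o$mse,
           n_included = o$entry$n_included, n_excluded = o$entry$n_excluded,
           summary = list(mean = o$entry$summary_mean,
                          min = o$entry$summary_min,
                          max = o$entry$summary_max,
                          unit = if (o$kind == "geographic") "persons" else "m"))
    }))
  files <- c(files, write_json_12sig(report, file.path(out_dir, "optimal.json")))
  invisible(list(points = ps, density = prof, sweeps = sweeps, optima = optima,
                 files = files))
}
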