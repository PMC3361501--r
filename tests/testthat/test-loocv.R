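f1 <- make_fixture("F1")

test_that("per-point error is the squared gap between test and training proportions", {
  rec <- point_error(geographic_filter(f1, "A", 15))
  expect_equal(rec$p, 0.5)
  expect_equal(rec$q, 1)
  expect_equal(rec$squared_error, 0.25)

  # p = 0 against q = 1 is the maximal disagreement
  rec_c <- point_error(geographic_filter(f1, "C", 15))
  expect_equal(rec_c$p, 0)
  expect_equal(rec_c$q, 1)
  expect_equal(rec_c$squared_error, 1)

  # equal proportions give zero error
  ps <- point_set(c("A", "B"), c(0, 1), c(0, 0), c(2, 4), c(1, 2))
  expect_equal(point_error(geographic_filter(ps, "A", 5))$squared_error, 0)

  # an empty training set yields an excluded record with no error
  rec_x <- point_error(geographic_filter(f1, "A", 5))
  expect_identical(rec_x$excluded, "empty_training")
  expect_true(is.na(rec_x$squared_error))
})

test_that("the F1 worked example gives MSE 29/48 at radius 15", {
  entry <- loocv_mse(f1, filter_spec("geographic", 15))
  expect_identical(entry$mse, 29 / 48)
  expect_equal(entry$n_included, 3)
  expect_equal(entry$n_excluded, 0)
  expect_equal(entry$summary_min, 6)   # captured population ranges 6..8
  expect_equal(entry$summary_max, 8)
})

test_that("identical outcome proportions everywhere give zero MSE at every filter", {
  set.seed(4)
  ps <- random_ps(40, "clustered")
  ps$positives <- ps$population * 0.5  # exact half coverage at every point
  ps <- as_point_set(as.data.frame(ps))
  for (kind in c("geographic", "nearly_fixed_population")) {
    sizes <- if (kind == "geographic") c(30, 120, 700) else c(10, 40, 100)
    curve <- suppressWarnings(sweep_filters(ps, kind, sizes))
    expect_true(all(curve$mse[curve$valid] == 0))
  }
})

test_that("a radius below all nearest-neighbor gaps invalidates the entry", {
  entry <- loocv_mse(f1, filter_spec("geographic", 5))
  expect_false(entry$valid)
  expect_true(is.na(entry$mse))
  expect_equal(entry$n_excluded, 3)
  expect_error(select_optimal(sweep_filters(f1, "geographic", c(1, 5))),
               "no valid entries")
})

test_that("sweep entries match one-at-a-time computation and the naive oracle", {
  ps <- random_ps(70, "clustered", seed = 31)
  grid <- c(20, 60, 150, 400)
  curve <- suppressWarnings(sweep_filters(ps, "geographic", grid))
  expect_equal(curve$size, grid)  # grid order preserved
  for (j in seq_along(grid)) {
    single <- suppressWarnings(loocv_mse(ps, filter_spec("geographic", grid[j])))
    expect_identical(single$mse, curve$mse[j])
    ref <- naive_loocv_entry(ps, "geographic", grid[j])
    expect_equal(curve$mse[j], ref$mse, tolerance = 1e-12)
    expect_equal(curve$n_included[j], ref$n_included)
    expect_equal(curve$summary_mean[j], ref$summary_mean, tolerance = 1e-12)
  }
  # population kinds, including the fractionated one
  for (kind in c("nearly_fixed_population", "fixed_population")) {
    pgrid <- c(15, 60, 200)
    pc <- suppressWarnings(sweep_filters(ps, kind, pgrid))
    for (j in seq_along(pgrid)) {
      ref <- naive_loocv_entry(ps, kind, pgrid[j])
      expect_equal(pc$mse[j], ref$mse, tolerance = 1e-12)
      expect_equal(pc$summary_max[j], ref$summary_max, tolerance = 1e-12)
    }
  }
})

test_that("optimum selection takes the minimal MSE and breaks ties to the smaller size", {
  curve <- sweep_filters(make_fixture("F2"), "geographic", c(10, 25, 45))
  opt <- select_optimal(curve)
  expect_equal(opt$mse, min(curve$mse[curve$valid]))
  # engineered tie: identical proportions make every entry 0; smallest wins
  ps <- point_set(c("A", "B", "C"), c(0, 10, 20), c(0, 0, 0),
                  c(2, 2, 2), c(1, 1, 1))
  tie <- sweep_filters(ps, "geographic", c(100, 200))
  expect_equal(select_optimal(tie)$size, 100)
})

test_that("MSE lies in [0,1] and is invariant to relabeling, rigid motion and outcome complement", {
  ps <- random_ps(60, "clustered", seed = 8)
  grid <- c(25, 80, 250)
  base <- suppressWarnings(sweep_filters(ps, "geographic", grid))
  expect_true(all(base$mse[base$valid] >= 0 & base$mse[base$valid] <= 1))

  mv <- rigid_motion(ps, 1.234, 5000, -3000)
  moved <- suppressWarnings(sweep_filters(mv, "geographic", grid))
  expect_equal(moved$mse, base$mse, tolerance = 1e-9)

  flip <- ps
  flip$positives <- flip$population - flip$positives
  flip <- as_point_set(as.data.frame(flip))
  flipped <- suppressWarnings(sweep_filters(flip, "geographic", grid))
  expect_equal(flipped$mse, base$mse, tolerance = 1e-12)

  relab <- ps
  relab$id <- sprintf("z%04d", seq_len(nrow(ps)))  # fixture has no distance ties
  relab <- as_point_set(as.data.frame(relab))
  relabeled <- suppressWarnings(sweep_filters(relab, "geographic", grid))
  expect_equal(relabeled$mse, base$mse, tolerance = 1e-12)
})

test_that("default grids follow the two-regime conventions", {
  expect_equal(geographic_grid(), c(seq(50, 200, 50), seq(400, 2000, 200)))
  expect_length(geographic_grid(), 13)
  expect_equal(geographic_grid(dense = TRUE)[1:3], c(10, 20, 30))
  expect_length(population_grid(), 33)
  expect_error(sweep_filters(f1, "geographic", numeric(0)), "non-empty")
})
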