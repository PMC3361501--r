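f1 <- make_fixture("F1")
f2 <- make_fixture("F2")

test_that("geographic filter captures the closed ball around the center", {
  cap <- geographic_filter(f1, "A", radius = 15)
  expect_equal(cap$test_population, 2)
  expect_equal(cap$test_positives, 1)
  expect_equal(cap$training_members$point_id, "B")
  expect_equal(cap$training_population, 4)
  expect_equal(cap$training_positives, 4)
  expect_equal(cap$achieved_population, 6)
  expect_equal(cap$achieved_radius_m, 10)

  # boundary is closed: a point exactly at the radius is captured
  at10 <- geographic_filter(f1, "A", radius = 10)
  expect_equal(at10$training_members$point_id, "B")

  # radius below every nearest-neighbor gap leaves the training set empty
  tiny <- geographic_filter(f1, "B", radius = 5)
  expect_equal(nrow(tiny$training_members), 0)
  expect_identical(tiny$excluded_reason, "empty_training")

  # radius covering the study area captures everyone
  all_cap <- geographic_filter(f1, "C", radius = 1e6)
  expect_equal(all_cap$achieved_population, total_population(f1))
})

test_that("nearly fixed population filter stops at the first prefix reaching the target", {
  cap <- nearly_fixed_population_filter(f2, "C", target = 7)
  expect_equal(cap$training_members$point_id, c("B", "D"))
  expect_equal(cap$training_population, 10)
  expect_equal(cap$training_positives, 7)
  expect_equal(cap$achieved_population, 12)
  expect_true(cap$achieved_population >= 7)

  # center alone meets the target: empty training, flagged for exclusion
  solo <- nearly_fixed_population_filter(f2, "D", target = 5)
  expect_equal(nrow(solo$training_members), 0)
  expect_identical(solo$excluded_reason, "empty_training")

  # target equal to the total population exhausts the set exactly
  full <- nearly_fixed_population_filter(f2, "A", target = total_population(f2))
  expect_equal(full$achieved_population, total_population(f2))
  expect_true(is.na(full$excluded_reason))

  # unreachable target captures everything and is flagged
  over <- nearly_fixed_population_filter(f2, "A", target = 100)
  expect_identical(over$excluded_reason, "target_unreached")
  expect_equal(over$achieved_population, total_population(f2))
})

test_that("fixed population filter fractionates only the last training point", {
  cap <- fixed_population_filter(f2, "C", target = 7)
  expect_equal(cap$training_members$point_id, c("B", "D"))
  expect_equal(cap$training_members$weight, c(1, 1 / 6))
  expect_equal(cap$training_population, 5)
  expect_equal(cap$training_positives, 4.5)
  expect_equal(cap$achieved_population, 7)

  # a target landing exactly on a prefix sum needs no fractionation
  exact <- fixed_population_filter(f2, "C", target = 6)
  near <- nearly_fixed_population_filter(f2, "C", target = 6)
  expect_equal(exact$training_members$weight, 1)
  expect_equal(exact$training_population, near$training_population)
  expect_equal(exact$training_positives, near$training_positives)

  expect_error(fixed_population_filter(f2, "A", target = 1000),
               "exceeds the total population")
})

test_that("the target_includes_center switch shifts the accumulation threshold", {
  # target 4 from center C (pop 2): counting the center, C+B suffices;
  # counting only training individuals, B alone (pop 4) already meets it
  with_c <- nearly_fixed_population_filter(f2, "C", 4)
  expect_equal(with_c$training_members$point_id, "B")
  without_c <- nearly_fixed_population_filter(f2, "C", 5,
                                              target_includes_center = FALSE)
  expect_equal(without_c$training_members$point_id, c("B", "D"))
  # fixed kind: the weighted *training* population then equals the target
  fp <- fixed_population_filter(f2, "C", 5, target_includes_center = FALSE)
  expect_equal(fp$training_population, 5)
})

test_that("filter invariants hold on random centers and sizes", {
  ps <- random_ps(80, "clustered", seed = 21)
  tot <- total_population(ps)
  set.seed(99)
  for (rep in 1:100) {
    id <- sample(ps$id, 1)
    target <- runif(1, 1, tot)
    nf <- nearly_fixed_population_filter(ps, id, target)
    # achieved >= target with a minimal prefix
    expect_gte(nf$achieved_population, target)
    last_pop <- if (nrow(nf$training_members) > 0) {
      ps$population[match(utils::tail(nf$training_members$point_id, 1), ps$id)]
    } else nf$test_population
    expect_lt(nf$achieved_population - last_pop, target)

    fp <- fixed_population_filter(ps, id, target)
    if (nrow(fp$training_members) > 0) {
      # defining property: the weighted head-count hits the target exactly
      expect_equal(fp$achieved_population, target, tolerance = 1e-9)
      expect_true(all(fp$training_members$weight > 0 &
                      fp$training_members$weight <= 1))
      expect_true(all(fp$training_members$weight[-nrow(fp$training_members)] == 1))
    }

    # geographic capture monotone in radius
    r1 <- runif(1, 1, 400); r2 <- r1 + runif(1, 0, 300)
    g1 <- geographic_filter(ps, id, r1)
    g2 <- geographic_filter(ps, id, r2)
    expect_true(all(g1$training_members$point_id %in% g2$training_members$point_id))

    # population prefixes monotone in target
    t2 <- target + runif(1, 0, tot - target)
    nf2 <- nearly_fixed_population_filter(ps, id, t2)
    k1 <- nrow(nf$training_members)
    expect_identical(nf$training_members$point_id,
                     nf2$training_members$point_id[seq_len(k1)])
  }
})

test_that("capture bookkeeping is consistent: unweighted populations add up", {
  ps <- random_ps(50, seed = 5)
  set.seed(7)
  for (rep in 1:20) {
    id <- sample(ps$id, 1)
    cap <- geographic_filter(ps, id, runif(1, 5, 600))
    members <- c(id, cap$training_members$point_id)
    expect_equal(cap$achieved_population,
                 sum(ps$population[match(members, ps$id)]))
    expect_equal(cap$achieved_radius_m,
                 max(0, naive_dist_matrix(ps)[match(id, ps$id),
                                              match(members, ps$id)]))
  }
})
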