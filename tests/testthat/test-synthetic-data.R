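test_that("neutral scenario has flat elevation surfaces and site-invariant true lambda", {
  pool <- species_pool(1, 1, "neutral", seed = 1)
  for (spec in pool) {
    expect_identical(unname(spec$surv["elev"]), 0)
    expect_identical(unname(spec$grow["elev"]), 0)
    expect_identical(unname(spec$fec["elev"]), 0)
  }
  lams <- vapply(c(890, 1400, 1900), function(e)
    true_lambda(pool[[1]], e), numeric(1))
  expect_equal(lams[1], lams[2], tolerance = 1e-12)
  expect_equal(lams[1], lams[3], tolerance = 1e-12)
})

test_that("pools and datasets are reproducible under a fixed seed", {
  p1 <- species_pool(2, 2, "facilitation_mix", seed = 7)
  p2 <- species_pool(2, 2, "facilitation_mix", seed = 7)
  expect_identical(p1, p2)
  des <- experiment_design(species_ids = names(p1), n_individuals = 5,
                           n_transitions = 2, seed = 3)
  d1 <- simulate_individuals(p1, des)
  d2 <- simulate_individuals(p1, des)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$recruitment, d2$recruitment)
})

test_that("unknown scenarios and species are rejected", {
  expect_error(species_pool(1, 1, "bogus", seed = 1))
  pool <- species_pool(1, 1, "neutral", seed = 1)
  des <- experiment_design(pair_list = data.frame(focal = "ghost",
                                                  background = "none"),
                           seed = 1)
  expect_error(simulate_individuals(pool, des), "unknown species")
})

test_that("degenerate noise yields certain survival at the deterministic growth mean", {
  pool <- species_pool(1, 1, "neutral", seed = 2)
  spec <- pool[[1]]
  spec$surv["intercept"] <- 50   # survival probability ~ 1 at any size
  spec$grow_sd <- 1e-9
  pool[[1]] <- spec
  des <- experiment_design(site_elevations = 1400,
                           pair_list = data.frame(focal = spec$species_id,
                                                  background = "none"),
                           n_individuals = 30, n_transitions = 1, seed = 9)
  ds <- simulate_individuals(pool, des)
  expect_true(all(ds$records$survived == 1L))
  vr <- true_vital_rates(spec, 1400)
  expect_equal(ds$records$size_t1, vr$grow_mean(ds$records$size_t),
               tolerance = 1e-6)
})

test_that("empirical survival converges to the true inverse-link probabilities", {
  pool <- species_pool(1, 1, "neutral", seed = 6)
  spec <- pool[[1]]
  des <- experiment_design(site_elevations = 1400,
                           pair_list = data.frame(focal = spec$species_id,
                                                  background = "none"),
                           n_individuals = 500, n_transitions = 1, seed = 21)
  ds <- simulate_individuals(pool, des)
  vr <- true_vital_rates(spec, 1400)
  p <- vr$surv(ds$records$size_t)
  se <- sqrt(mean(p) * (1 - mean(p)) / nrow(ds$records))
  expect_lt(abs(mean(ds$records$survived) - mean(p)), 3 * se)
})

test_that("range-limited lowland species decline in true lambda beyond their upper edge", {
  pool <- species_pool(7, 7, "range_limited", seed = 3)
  low <- Filter(function(s) s$origin == "lowland", pool)
  for (spec in low)
    expect_lt(true_lambda(spec, 1900), true_lambda(spec, 890))
  high <- Filter(function(s) s$origin == "highland", pool)
  for (spec in high)
    expect_lt(true_lambda(spec, 890), true_lambda(spec, 1900))
})

test_that("dead individuals are replaced as flagged new individuals", {
  pool <- species_pool(1, 1, "neutral", seed = 4)
  spec <- pool[[1]]
  spec$surv["intercept"] <- -3   # high mortality
  pool[[1]] <- spec
  des <- experiment_design(site_elevations = 890,
                           pair_list = data.frame(focal = spec$species_id,
                                                  background = "none"),
                           n_individuals = 30, n_transitions = 3, seed = 13)
  ds <- simulate_individuals(pool, des)
  r <- ds$records
  expect_true(any(r$is_replacement == 1L))
  # replacements enter one census after a death, with fresh ids
  y1 <- r[r$year == 1, ]; y2 <- r[r$year == 2, ]
  expect_equal(sum(y2$is_replacement == 1L), sum(y1$survived == 0L))
  expect_false(any(y2$individual_id[y2$is_replacement == 1L] %in%
                     y1$individual_id))
})

test_that("dropped monoculture combinations are omitted from the records", {
  pool <- species_pool(1, 1, "neutral", seed = 5)
  ids <- names(pool)
  des <- experiment_design(species_ids = ids, n_individuals = 3,
                           n_transitions = 1,
                           drop_combinations = data.frame(
                             background = ids[1], site_elevation_m = 890),
                           seed = 2)
  ds <- simulate_individuals(pool, des)
  expect_false(any(ds$records$background == ids[1] &
                     ds$records$site_elevation_m == 890))
  expect_true(any(ds$records$background == ids[1] &
                    ds$records$site_elevation_m == 1400))
})

test_that("datasets round-trip through CSV output", {
  pool <- species_pool(1, 1, "neutral", seed = 1)
  des <- experiment_design(species_ids = names(pool), n_individuals = 3,
                           n_transitions = 1, seed = 1)
  ds <- simulate_individuals(pool, des)
  dir <- tempfile("coexipm")
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  rt <- utils::read.csv(paths[1])
  expect_equal(nrow(rt), nrow(ds$records))
  expect_equal(rt$size_t, ds$records$size_t, tolerance = 1e-12)
})
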