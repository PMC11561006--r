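test_that("the river density cap follows from the transect counts", {
  expect_equal(compute_K(17, 15, 10), 17 / 150)
  expect_equal(format_density(compute_K(17, 15, 10)), "0.113")
  expect_equal(compute_K(0, 15, 10), 0)
  expect_equal(compute_K(30, 15, 10), 0.2)
  expect_error(compute_K(17, 0, 10), "positive")
  expect_error(compute_K(1.5, 15, 10), "integer")
})

test_that("transect length converts to whole cells, warning otherwise", {
  expect_identical(transect_cells(75, 5), 15L)
  expect_identical(transect_cells(5, 5), 1L)
  expect_identical(transect_cells(100, 5), 20L)
  expect_warning(got <- transect_cells(77, 5), "rounding down")
  expect_identical(got, 15L)
  expect_error(transect_cells(-1, 5), "positive")
})

test_that("parcel expectation sums the fitted density over the parcels", {
  geo <- column_river_geom(8, 9, 1)
  parcels <- parcel_set(rbind(c(2, 3), c(4, 5), c(6, 7), c(1, 2), c(3, 4)),
                        total_year_count = 3, n_trips = 10)
  s <- state_constant(geo, 0.113)
  expect_equal(parcel_expectation(s, parcels), 5 * 0.113)
  expect_equal(parcel_expectation(state_constant(geo, 0), parcels), 0)
  # a parcel on the river is outside every region
  bad <- parcel_set(rbind(c(2, 0)))
  expect_error(parcel_expectation(s, bad), "region")
  expect_equal(tacana_preset()$parcel_target, 0.3)
})

test_that("T1 selection returns the argmin of the tail energies", {
  geo <- column_river_geom(10, 11, 1)
  cands <- c(1e-3, 1e-4, 1e-5)
  sel <- select_T1(cands, geo, 1, K_CASE, n_sweeps = 1500, tail_sweeps = 150,
                   seed = 3)
  expect_equal(nrow(sel$table), 3)
  expect_equal(sel$T1, sel$table$T[which.min(sel$table$tail_energy)])
  expect_true(all(sel$table$tail_energy >=
                    min(sel$table$tail_energy)))
  expect_false(anyNA(sel$warm_state[geo$label == 1]))
  single <- select_T1(1e-4, geo, 1, K_CASE, n_sweeps = 500, tail_sweeps = 50,
                      seed = 3)
  expect_equal(single$T1, 1e-4)
})

test_that("g calibration matches a halved parcel expectation on a synthetic region", {
  geo <- column_river_geom(12, 13, 1)
  parcels <- parcel_set(rbind(c(3, 4), c(7, 8), c(10, 10)), n_trips = 10)
  free <- two_stage_chain(geo, 1, K_CASE, 0, 1e-5, 1e-7, 20000, 500, seed = 0)
  e0 <- parcel_expectation(free$omega_hat, parcels)
  target <- 0.5 * e0
  cal <- estimate_g(target, parcels, geo, 1, K_CASE, 1e-5, 1e-7,
                    n_sweeps = 20000, tail_sweeps = 500, seed = 0,
                    tol = 0.02 * target)
  expect_s3_class(cal, "calibration_result")
  expect_gt(cal$g_hat, 0)
  expect_lte(abs(cal$achieved_parcel_expectation - target), 0.02 * target)
  expect_gte(nrow(cal$evaluations), 2)
  # the evaluation trace is monotone in g up to Monte-Carlo wiggle
  ev <- cal$evaluations[order(cal$evaluations$g), ]
  expect_true(all(diff(ev$expectation) <= 0.1 * e0))
})

test_that("a target at the free-case expectation is matched by g ~ 0", {
  geo <- column_river_geom(10, 11, 1)
  parcels <- parcel_set(rbind(c(2, 3), c(5, 6)), n_trips = 10)
  free <- two_stage_chain(geo, 1, K_CASE, 0, 1e-4, 1e-6, 1500, 150, seed = 1)
  e0 <- parcel_expectation(free$omega_hat, parcels)
  cal <- estimate_g(e0, parcels, geo, 1, K_CASE, 1e-4, 1e-6,
                    n_sweeps = 1500, tail_sweeps = 150, seed = 1, tol = 0.05)
  expect_equal(cal$g_hat, 0)
  expect_equal(cal$achieved_parcel_expectation, e0)
})

test_that("an unreachable target is an infeasibility error", {
  geo <- column_river_geom(10, 11, 1)
  parcels <- parcel_set(rbind(c(2, 3), c(5, 6)), n_trips = 10)
  expect_error(
    estimate_g(10, parcels, geo, 1, K_CASE, 1e-4, 1e-6,
               n_sweeps = 500, tail_sweeps = 50, seed = 1),
    "infeasible")
})

test_that("g calibration is deterministic given the seed and configuration", {
  geo <- column_river_geom(10, 11, 1)
  parcels <- parcel_set(rbind(c(2, 3), c(5, 6)), n_trips = 10)
  free <- two_stage_chain(geo, 1, K_CASE, 0, 1e-5, 1e-7, 8000, 200, seed = 4)
  target <- 0.6 * parcel_expectation(free$omega_hat, parcels)
  a <- estimate_g(target, parcels, geo, 1, K_CASE, 1e-5, 1e-7,
                  n_sweeps = 8000, tail_sweeps = 200, seed = 4, tol = 0.01)
  b <- estimate_g(target, parcels, geo, 1, K_CASE, 1e-5, 1e-7,
                  n_sweeps = 8000, tail_sweeps = 200, seed = 4, tol = 0.01)
  expect_identical(a$g_hat, b$g_hat)
  expect_identical(a$evaluations, b$evaluations)
})
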