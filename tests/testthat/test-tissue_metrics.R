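test_that("solute mass is concentration times simultaneous plasma volume", {
  # group-mean product: 31.4 g/l * 60.9 ml/kg -> 1.91 g/kg (the study's group
  # value, a mean of per-animal products, differs slightly by construction)
  expect_equal(solute_mass(31.4, 60.9 * 42, 42), 31.4 * 60.9 / 1000)
  expect_equal(solute_mass(31.4, 60.9 * 42, 42), 1.91, tolerance = 2e-3)
  expect_equal(solute_mass(0, 2500, 40), 0)
  expect_equal(solute_mass(40, 2500, 40), 2.5)
  # round trip back to concentration
  expect_equal(solute_mass(47, 2604, 42) * 42 / (2604 / 1000), 47)
})

test_that("reference-sample flow scales counts by the withdrawal rate", {
  expect_equal(microsphere_flow(500, 2.5, 10000, 2), 4)
  expect_equal(microsphere_flow(0, 2.5, 10000, 2), 0)
  # a sample capturing as many spheres as the reference, per 100 g, flows q_ref
  expect_equal(microsphere_flow(10000, 100, 10000, 2), 2)
  # linear in counts and rate, inverse in mass
  expect_equal(microsphere_flow(1000, 2.5, 10000, 2),
               2 * microsphere_flow(500, 2.5, 10000, 2))
  expect_equal(microsphere_flow(500, 5, 10000, 2),
               microsphere_flow(500, 2.5, 10000, 2) / 2)
  expect_error(microsphere_flow(500, 2.5, 0, 2), "no reference spheres")
})

test_that("tissue water is weight lost on drying per gram dry weight", {
  expect_equal(tissue_water(500, 100), 4)
  expect_equal(tissue_water(100, 100), 0)
  expect_equal(tissue_water(621, 100), 5.21)
  expect_error(tissue_water(90, 100), "wet mass below dry")
  expect_warning(tissue_water(1200, 100), "above 10")
})

test_that("derived indices follow the conventional dyne/pressure formulas", {
  dh <- derived_hemodynamics(65.8, 8.0, 20.0, 11.0, 16.3, co = 5.1)
  expect_equal(dh$svr, 80 * (65.8 - 8.0) / 5.1) # ~906, Table-1 scale
  expect_equal(dh$svr, 906.7, tolerance = 1e-3)
  expect_equal(dh$pvr, 80 * 9 / 5.1)
  expect_equal(dh$cpp, 65.8 - 16.3)
  expect_equal(derived_hemodynamics(60, 5, 20, 10, 60, 5)$cpp, 0)
  expect_error(derived_hemodynamics(60, 5, 20, 10, 16, 0), "cardiac output")
})

test_that("lactate/pyruvate ratio is unit-consistent by default", {
  dh <- derived_hemodynamics(60, 5, 20, 10, 16, 5,
                             lactate_mmol_l = 3.5, pyruvate_umol_l = 212)
  expect_equal(dh$lp_ratio, 3.5 / 0.212)
  expect_equal(dh$lp_ratio, 16.5, tolerance = 1e-2)
  raw <- derived_hemodynamics(60, 5, 20, 10, 16, 5, 3.5, 212,
                              lp_units = "raw")
  expect_equal(raw$lp_ratio, 3.5 / 212)
})

test_that("percent change is computed per animal, then averaged", {
  expect_equal(percent_change(3.063, 1.540), 49.72, tolerance = 1e-3)
  expect_equal(percent_change(2, 1), 50)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero baseline")
  g <- group_percent_change(c(2, 4), c(1, 1))
  expect_equal(g$mean, mean(c(50, 75)))
  expect_equal(g$n, 2)
})

test_that("recovered aliquot flows stay within the cardiac output budget", {
  set.seed(11)
  ds <- simulate_cohort(1, 1, "trajectory", master_seed = 3)
  ms <- ds$microspheres
  flows <- microsphere_flow(ms$n_spheres, ms$sample_mass_g, ms$n_ref,
                            ms$q_ref_ml_min)
  co_ml <- sim_params()$microspheres$cardiac_output_ml_min
  for (key in split(seq_len(nrow(ms)), ms[c("animal_id", "phase")])) {
    expect_lt(sum(flows[key] * ms$sample_mass_g[key] / 100), co_ml)
  }
})
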