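test_that("CO-dilution estimate reproduces the hand-computed hemoglobin-mass chain", {
  # 17.6 ml CO / (1.39 * 0.05) = 253.24 g Hb; / 86 g/l -> 2944.6 ml blood;
  # * 0.277 -> 815.7 ml red cells
  rec <- co_dilution_record(17.6, 0.010, 0.060, cthb = 86, hct = 0.277)
  expect_equal(estimate_vrbc_co(rec), 17.6 / (1.39 * 0.05) / 86 * 1000 * 0.277)
  expect_equal(estimate_vrbc_co(rec), 815.7, tolerance = 1e-4)
})

test_that("CO-dilution estimate is homogeneous in dose and label uptake", {
  base <- estimate_vrbc_co(co_dilution_record(10, 0.01, 0.05, 90, 0.3))
  expect_equal(estimate_vrbc_co(co_dilution_record(20, 0.01, 0.05, 90, 0.3)),
               2 * base)
  # degree -1 in the COHb rise
  expect_equal(estimate_vrbc_co(co_dilution_record(10, 0.01, 0.09, 90, 0.3)),
               base / 2)
  # the Huefner constant is exposed
  expect_equal(estimate_vrbc_co(co_dilution_record(10, 0.01, 0.05, 90, 0.3),
                                hufner = 1.36),
               base * 1.39 / 1.36)
})

test_that("degenerate or invalid dilution records are refused", {
  expect_error(co_dilution_record(10, 0.05, 0.05, 90, 0.3),
               "no measurable label uptake")
  expect_error(co_dilution_record(10, 0.06, 0.05, 90, 0.3),
               "no measurable label uptake")
  expect_error(co_dilution_record(-1, 0.01, 0.05, 90, 0.3), "co_dose")
  expect_error(co_dilution_record(10, 0.01, 0.05, 0, 0.3), "cthb")
  expect_error(co_dilution_record(10, 0.01, 0.05, 90, 1.2), "hct")
})

test_that("red-cell propagation books losses as volume times hematocrit", {
  grid <- seq(-60, 240, 30)
  ev <- data.frame(time = 0, volume = 30, hct = 0.30)
  vs <- update_vrbc(816, ev, grid)
  expect_equal(vs$vrbc[grid < 0], rep(816, 2))
  expect_equal(vs$vrbc[grid >= 0], rep(816 - 9, 9))
  # no events and zero-volume events leave the series untouched
  expect_equal(update_vrbc(816, NULL, grid)$vrbc, rep(816, 11))
  expect_equal(update_vrbc(816, data.frame(time = 0, volume = 0, hct = 0.3),
                           grid)$vrbc, rep(816, 11))
})

test_that("red cells are conserved exactly over arbitrary event lists", {
  set.seed(71)
  for (k in 1:25) {
    n_ev <- sample(0:12, 1)
    ev <- data.frame(time = sort(runif(n_ev, -60, 240)),
                     volume = runif(n_ev, 0, 20),
                     hct = runif(n_ev, 0.2, 0.4))
    vs <- update_vrbc(900, ev, seq(-60, 240, 30))
    expect_identical(vs$vrbc[11], 900 - sum(ev$volume * ev$hct))
    expect_true(all(diff(vs$vrbc) <= 0))
  }
})

test_that("exhausting the red-cell volume is an explicit bookkeeping error", {
  ev <- data.frame(time = c(0, 30), volume = c(2000, 2000), hct = c(0.3, 0.3))
  expect_error(update_vrbc(816, ev, seq(-60, 240, 30)), "exhausted")
})

test_that("plasma volume inverts hematocrit exactly", {
  expect_equal(plasma_volume(100, 0.25), 300)
  expect_equal(plasma_volume(816, 0.5), 816)
  # inversion of the intervention-group baseline: 23.3 ml/kg at 27.7%
  expect_equal(plasma_volume(23.3, 0.277), 60.8, tolerance = 1e-3)
  # round trip to machine precision across the physiologic range
  h <- seq(0.05, 0.95, by = 0.05)
  expect_equal(plasma_volume(500, h) * h / (1 - h), rep(500, length(h)))
  expect_error(plasma_volume(500, 1.1), "hct")
  expect_error(plasma_volume(-5, 0.3), "vrbc")
})

test_that("missing interior hematocrit is interpolated, edges are not extrapolated", {
  t <- seq(0, 120, 30)
  expect_equal(fill_hct(t, c(0.30, NA, 0.32, NA, 0.36)),
               c(0.30, 0.31, 0.32, 0.34, 0.36))
  expect_error(fill_hct(t, c(NA, 0.3, 0.3, 0.3, 0.3)), "extrapolation")
  expect_error(fill_hct(t, c(0.3, 0.3, 0.3, 0.3, NA)), "extrapolation")
})

test_that("volume series combines tracer baseline, ledger and hematocrit", {
  t <- seq(-60, 0, 30)
  vs <- volume_series(800, t, c(0.30, NA, 0.32),
                      events = data.frame(time = 0, volume = 20, hct = 0.32),
                      weight = 40)
  expect_equal(vs$vrbc, c(800, 800, 800 - 6.4))
  expect_equal(vs$pv, vs$vrbc * (1 - vs$hct) / vs$hct)
  expect_equal(vs$pv_per_kg, vs$pv / 40)
})
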