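test_that("nu arithmetic matches the defining ratio on printed-scale inputs", {
  # a 10-yr surface loss of 0.09 kg C m-2 under +1.1 degC soil warming
  expect_equal(nu_from_stocks(-90, 0, 1.1, 10), -90 / 1.1 / 10,
               tolerance = 1e-12)
  expect_equal(nu_from_stocks(-90, 0, 1.1, 10), -8.181818181818,
               tolerance = 1e-9)
  # kg input converts to g-scale output
  expect_equal(nu_from_stocks(-0.09, 0, 1.1, 10, units = "kg"),
               nu_from_stocks(-90, 0, 1.1, 10))
  # identity and symmetry
  expect_equal(nu_from_stocks(5, 5, 1.1, 10), 0)
  expect_equal(nu_from_stocks(-90, 0, -1.1, 10), -nu_from_stocks(-90, 0, 1.1, 10))
})

test_that("compute_nu matches an independent recomputation to 1e-12", {
  p <- step_pair("foothills-tundra")
  for (d in c(0.1, 0.6)) {
    got <- compute_nu(p$step, p$control, d, c(2000, 2010))
    expect_true(got$valid)
    expect_equal(got$nu, oracle_nu(p$step, p$control, d, c(2000, 2010)),
                 tolerance = 1e-12)
  }
  rp <- ramp_pair("cold-coastal-tundra")
  got <- compute_nu(rp$ramp, rp$control, 0.1, c(2090, 2100))
  expect_equal(got$nu, oracle_nu(rp$ramp, rp$control, 0.1, c(2090, 2100)),
               tolerance = 1e-12)
})

test_that("nu is homogeneous of degree -1 in the window length", {
  expect_equal(nu_from_stocks(-90, 0, 1.1, 20),
               nu_from_stocks(-90, 0, 1.1, 10) / 2)
})

test_that("a run against itself gives zero (or frozen) everywhere and never a division artefact", {
  run <- cached_run("cold-coastal-tundra", "control", 10, 11)
  prof <- nu_profile(run, run, list(c(2000, 2010)))
  expect_equal(nrow(prof), 4)
  # delta T is exactly 0 against itself: every non-frozen cell is invalid
  for (i in seq_len(nrow(prof))) {
    expect_true(prof$frozen[i] || !prof$valid[i])
    if (prof$frozen[i]) expect_identical(prof$nu[i], 0)
  }
})

test_that("layers below the thaw front in both runs are flagged frozen with nu = 0", {
  p <- step_pair("cold-coastal-tundra")   # ald stays well above 1.0 m
  got <- compute_nu(p$step, p$control, 1.7, c(2000, 2010))
  expect_true(got$frozen)
  expect_identical(got$nu, 0)
  expect_true(got$valid)
  # and the stock truly never changed there
  expect_equal(got$c_p, got$c_b)
})

test_that("sub-tolerance temperature contrasts are flagged invalid, not divided", {
  run1 <- cached_run("boreal-forest", "control", 5, 21)
  run2 <- cached_run("boreal-forest", "control", 5, 21)
  got <- compute_nu(run1, run2, 0.1, c(2000, 2005))
  expect_false(got$valid)
  expect_true(is.na(got$nu))
  expect_match(got$reason, "below tolerance")
})

test_that("nu_profile covers the full depth x window grid with scenario labels", {
  rp <- ramp_pair("cold-coastal-tundra")
  prof <- nu_profile(rp$ramp, rp$control,
                     list(c(2045, 2055), c(2090, 2100)))
  expect_equal(nrow(prof), 8)
  expect_setequal(unique(prof$depth), c(0.1, 0.6, 1.0, 1.7))
  expect_true(all(prof$scenario == "ramp"))
})

test_that("paper-shaped contrasts: step nu negative everywhere; sign flip and magnitude ordering", {
  # (a) decade step warming gives negative top-layer nu at all four archetypes
  for (nm in site_preset_names()) {
    p <- step_pair(nm)
    nu_s <- compute_nu(p$step, p$control, 0.1, c(2000, 2010))
    expect_true(nu_s$valid)
    expect_lt(nu_s$nu, 0)
  }
  # (b) the sink-transition archetype flips sign between step and ramp
  p <- step_pair("cold-coastal-tundra")
  rp <- ramp_pair("cold-coastal-tundra")
  nu_step <- compute_nu(p$step, p$control, 0.1, c(2000, 2010))$nu
  nu_ramp <- compute_nu(rp$ramp, rp$control, 0.1, c(2090, 2100))$nu
  expect_lt(nu_step, 0)
  expect_gt(nu_ramp, 0)
  # (c) the source archetype: short-term sensitivity several times larger
  p <- step_pair("foothills-tundra")
  rp <- ramp_pair("foothills-tundra")
  nu_step <- compute_nu(p$step, p$control, 0.1, c(2000, 2010))$nu
  nu_ramp <- compute_nu(rp$ramp, rp$control, 0.1, c(2090, 2100))$nu
  expect_gt(abs(nu_step), abs(nu_ramp))
})

test_that("mismatched grids and out-of-range windows raise errors", {
  a <- cached_run("boreal-forest", "control", 3, 4)
  b <- cached_run("foothills-tundra", "control", 3, 4)
  expect_error(compute_nu(a, b, 0.1, c(2000, 2003)), "site")
  expect_error(compute_nu(a, a, 0.35, c(2000, 2003)), "layer grid")
  expect_error(compute_nu(a, a, 0.1, c(2010, 2020)), "outside")
})
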