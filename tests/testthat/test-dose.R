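test_that("self-absorbed dose implements the MIRD self-dose formula", {
  nuc <- lu177()
  expect_equal(self_absorbed_dose(0, 73, nuc), 0)
  # whole-body electron-only dose at TIAC 50.49 h
  expect_equal(self_absorbed_dose(50.49, 73, nuc, 0), 0.0590, tolerance = 1e-3)
  # unit case: 1 h TIAC in 1 kg
  expect_equal(self_absorbed_dose(1, 1, nuc, 0), 0.0853, tolerance = 1e-3)
  expect_error(self_absorbed_dose(1, 0, nuc), "> 0 kg")
  expect_error(self_absorbed_dose(-1, 73, nuc), ">= 0")
})

test_that("dose agrees with numerical integration of power over time", {
  nuc <- lu177()
  set.seed(202)
  for (i in 1:25) {
    k <- sample(1:2, 1)
    a <- runif(k, 0.01, 1)
    lam <- log(2) / runif(k, 5, 150)
    mass <- runif(1, 0.05, 73)
    phi <- runif(1, 0, 1)
    f <- tac_fit("x", if (k == 1) "mono" else "bi", a, lam, 0, 6)
    d <- self_absorbed_dose(tiac(f), mass, nuc, phi)
    d_oracle <- dose_numeric(a, lam, mass, energy_per_decay(nuc, phi))
    expect_equal(d, d_oracle, tolerance = 1e-3)
  }
})

test_that("doses are linear in TIAC and inversely proportional to mass", {
  nuc <- lu177()
  d1 <- self_absorbed_dose(10, 2, nuc, 0.2)
  expect_equal(self_absorbed_dose(30, 2, nuc, 0.2), 3 * d1)
  expect_equal(self_absorbed_dose(10, 4, nuc, 0), self_absorbed_dose(10, 2, nuc, 0) / 2)
})

test_that("mass adaptation rescales the reference dose inversely", {
  expect_equal(mass_adapted_dose(0.5, 0.31, 0.31), 0.5)
  expect_equal(mass_adapted_dose(0.5, 0.31, 0.62), 0.25)
  expect_equal(mass_adapted_dose(0.5, 0.310, 0.400), 0.3875)
  expect_error(mass_adapted_dose(0.5, 0, 0.4), "> 0")
})

test_that("sphere photon absorbed fraction is monotone, bounded and anchored", {
  m <- 10^seq(-2, 5, by = 0.25)
  phi <- photon_absorbed_fraction_sphere(m)
  expect_true(all(diff(phi) > 0))
  expect_true(all(phi >= 0 & phi < 1))
  expect_lt(photon_absorbed_fraction_sphere(1e-6), 1e-3)  # vanishes with mass
  expect_gt(photon_absorbed_fraction_sphere(1000), photon_absorbed_fraction_sphere(1))
  # whole-body anchor of the parameterization
  expect_equal(photon_absorbed_fraction_sphere(73000), 0.35, tolerance = 0.01)
  expect_error(photon_absorbed_fraction_sphere(0), "> 0")
})

test_that("sphere dose is the unit-density self-dose with full electron absorption", {
  nuc <- lu177()
  # photon contribution excluded for the hand-checked value
  expect_equal(self_absorbed_dose(0.5, 0.010, nuc, 0), 4.27, tolerance = 2e-3)
  d10 <- sphere_dose(0.5, 10, nuc)
  expect_gt(d10, 4.26)  # photon term only adds
  # doubling mass at fixed TIAC roughly halves the dose (phi grows slightly)
  d20 <- sphere_dose(0.5, 20, nuc)
  expect_equal(d20 / d10, 0.5, tolerance = 0.01)
  expect_equal(sphere_dose(0, 10, nuc), 0)
})

test_that("whole-body-method marrow dose equals the whole-body electron self-dose", {
  f <- tac_fit("whole_body", "mono", 1.0, log(2) / 35, rss = 0, n_points = 6)
  res <- marrow_dose_wholebody(f)
  expect_equal(res$absorbed_dose_gy_per_gbq, 0.0590, tolerance = 1e-3)
  expect_equal(res$method, "marrow_wholebody")
  # halving the whole-body mass doubles the dose
  res2 <- marrow_dose_wholebody(f, phantom_masses(whole_body_kg = 36.5))
  expect_equal(res2$absorbed_dose_gy_per_gbq,
               2 * res$absorbed_dose_gy_per_gbq)
  f0 <- tac_fit("whole_body", "mono", 0, 0.02, rss = 0, n_points = 6)
  expect_equal(marrow_dose_wholebody(f0)$absorbed_dose_gy_per_gbq, 0)
})

test_that("blood-method marrow dose integrates the concentration curve", {
  # monoexponential blood curve constructed to have c_int = 0.02 h/L
  lam <- 0.1
  a <- 0.02 * lam
  times <- c(0.5, 2, 4, 24, 48)
  x <- tac("blood", times, a * exp(-lam * times), "blood")
  res <- marrow_dose_blood(x, rmblr = 1)
  expect_equal(res$tiac_h, 0.0234, tolerance = 1e-3)
  expect_equal(res$absorbed_dose_gy_per_gbq, 1.71e-3, tolerance = 2e-3)
  expect_equal(res$method, "marrow_blood")
  # dose is linear in the marrow-to-blood ratio
  res2 <- marrow_dose_blood(x, rmblr = 2)
  expect_equal(res2$absorbed_dose_gy_per_gbq,
               2 * res$absorbed_dose_gy_per_gbq, tolerance = 1e-10)
  expect_error(marrow_dose_blood(tac("blood", 1:2, c(1, 0.5), "blood")),
               "at least 3")
})

test_that("phantom masses default to the ICRP-89 adult and accept overrides", {
  p <- phantom_masses()
  expect_equal(p$whole_body_kg, 73)
  expect_equal(p$kidneys_kg, 0.310)
  expect_equal(p$red_marrow_kg, 1.17)
  expect_equal(phantom_masses(kidneys_kg = 0.4)$kidneys_kg, 0.4)
  expect_error(phantom_masses(spleen_kg = 0.15), "unknown")
  expect_error(dose_result("x", 0.5, 0, 1, "sphere"), "zero exactly")
})
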