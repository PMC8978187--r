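test_that("region activity evaluates the decaying retention function", {
  p <- make_test_patient(te_wb = 34.95307)
  # t = 0: sum of amplitudes
  expect_equal(region_activity(p, "whole_body", 0), 1.0)
  expect_equal(region_activity(p, "kidneys", 0), 0.05)
  # one effective half-life halves the whole-body curve
  # (T_bio 44.76 h under Lu-177 gives T_eff 34.95 h)
  te <- combine_half_lives(44.76, 159.53)
  p2 <- virtual_patient(5.8, list(region_kinetics("whole_body", 1.0, 44.76)),
                        c(whole_body = 73))
  expect_equal(region_activity(p2, "whole_body", te), 0.5, tolerance = 1e-10)
  # biexponential decay limit
  p3 <- virtual_patient(5.8, list(
    region_kinetics("whole_body", c(0.5, 0.5), c(10, 100))),
    c(whole_body = 73))
  expect_lt(region_activity(p3, "whole_body", 1e5), 1e-12)
  expect_error(region_activity(p, "spleen", 1), "unknown region")
  expect_error(region_activity(p, "whole_body", -1), ">= 0")
})

test_that("patient construction enforces the amplitude and mass invariants", {
  kin <- list(region_kinetics("whole_body", 0.5, 40),
              region_kinetics("kidneys", 0.7, 80))
  expect_error(virtual_patient(5.8, kin, c(whole_body = 73, kidneys = 0.31)),
               "exceed")
  expect_error(virtual_patient(5.8, list(region_kinetics("kidneys", 0.1, 80)),
                               c(kidneys = 0.31)), "whole_body")
  expect_error(virtual_patient(5.8,
                               list(region_kinetics("whole_body", 1, 40),
                                    region_kinetics("kidneys", 0.1, 80)),
                               c(whole_body = 73)), "missing region mass")
  expect_error(region_kinetics("x", c(0.1, 0.2, 0.3), c(1, 2, 3)), "1 \\(mono\\) or 2")
  expect_error(region_kinetics("x", -0.1, 10), "non-negative")
})

test_that("planar simulation implements conjugate-view attenuation", {
  p <- make_test_patient()
  # no attenuation, noise off: anterior = posterior = activity x sens x dur
  pr0 <- acquisition_protocol(linear_attenuation = 0, noise = FALSE)
  s0 <- simulate_planar_series(p, pr0)
  act <- mapply(function(r, t) region_activity(p, r, t), s0$region, s0$time_h) *
    5.8 * 1000
  expect_equal(s0$anterior_counts, unname(act * 600 * 15))
  expect_equal(s0$anterior_counts, s0$posterior_counts)
  # mid-depth region with mu * thickness = 4 ln 2: geometric mean is
  # exp(-2 ln 2) = 0.25 of the unattenuated counts
  p2 <- make_test_patient()
  p2$body_thickness[] <- 4 * log(2) / 0.11
  pr <- acquisition_protocol(linear_attenuation = 0.11, noise = FALSE)
  s <- simulate_planar_series(p2, pr)
  gm <- sqrt(s$anterior_counts * s$posterior_counts)
  expect_equal(unname(gm / (act * 600 * 15)), rep(0.25, nrow(s)),
               tolerance = 1e-10)
})

test_that("Poisson noise is reproducible under the protocol seed", {
  p <- make_test_patient()
  pr <- acquisition_protocol(noise = TRUE, seed = 42)
  s1 <- simulate_planar_series(p, pr)
  s2 <- simulate_planar_series(p, pr)
  expect_identical(s1, s2)
  s3 <- simulate_planar_series(p, acquisition_protocol(noise = TRUE, seed = 43))
  expect_false(identical(s1$anterior_counts, s3$anterior_counts))
  # counts are integers under noise
  expect_true(all(s1$anterior_counts == round(s1$anterior_counts)))
})

test_that("SPECT measurement returns calibrated true activity", {
  p <- make_test_patient(a_k = 0.10, administered = 5.8)
  pr <- acquisition_protocol(spect_regions = "kidneys", spect_calibration = 1)
  expect_equal(simulate_spect(p, pr, "kidneys", t = 0), 580)
  pr8 <- acquisition_protocol(spect_regions = "kidneys", spect_calibration = 0.8)
  expect_equal(simulate_spect(p, pr8, "kidneys", t = 0), 464)
  expect_error(simulate_spect(p, pr, "whole_body"), "field of view")
  # zero retention gives zero activity
  p0 <- make_test_patient(a_k = 0)
  expect_equal(simulate_spect(p0, pr, "kidneys", t = 10), 0)
})

test_that("blood sampling divides retention by blood volume", {
  p <- make_test_patient(with_blood = TRUE)
  b0 <- simulate_blood_curve(p, 0)
  expect_equal(b0$fia_per_l, 1.0 / 5)  # bolus in 5 L
  # monoexponential blood: value halves after one effective half-life
  pm <- virtual_patient(5.8, list(region_kinetics("whole_body", 1, 40),
                                  region_kinetics("blood", 1.0, 44.76)),
                        c(whole_body = 73))
  te <- combine_half_lives(44.76, 159.53)
  expect_equal(simulate_blood_curve(pm, te)$fia_per_l, 0.1, tolerance = 1e-10)
  expect_equal(nrow(simulate_blood_curve(p, numeric(0))), 0)
  expect_error(simulate_blood_curve(make_test_patient(), c(1, 2)), "no blood")
})

test_that("total simulated activity never exceeds physical decay alone", {
  cohort <- simulate_reference_cohort(n_cycles = 3, seed = 11)
  lam_phys <- decay_constant(159.53)
  for (cy in cohort) {
    p <- cy$patient
    src <- setdiff(names(p$kinetics), c("whole_body", "blood"))
    for (t in c(0, 1, 24, 100, 500)) {
      bound <- exp(-lam_phys * t)
      expect_lte(region_activity(p, "whole_body", t), bound + 1e-12)
      total_src <- sum(vapply(src, function(r) region_activity(p, r, t), 0))
      expect_lte(total_src, bound + 1e-12)
    }
  }
})

test_that("acquisition protocol validates the clinical schedule", {
  expect_error(acquisition_protocol(scan_times = c(3, 24, 48, 72, 168)),
               "within 1 h")
  expect_error(acquisition_protocol(scan_times = c(0.5, 24, 48, 168)),
               "at least 5")
  expect_error(acquisition_protocol(scan_times = c(0.5, 24, 24, 48, 168)),
               "strictly increasing")
})
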