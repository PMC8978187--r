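test_that("monoexponential fit recovers noiseless parameters", {
  x <- make_mono_tac(a = 0.9, t_eff = 35, times = c(0.5, 3, 24, 48, 72))
  f <- fit_monoexp(x)
  expect_equal(f$amplitudes, 0.9, tolerance = 1e-6)
  expect_equal(f$effective_half_life, 35, tolerance = 1e-6)
  expect_equal(f$model, "mono")
  expect_lt(f$rss, 1e-20)
  # normalized whole-body curve: amplitude ~ 1
  f1 <- fit_monoexp(make_mono_tac(a = 1, t_eff = 30))
  expect_equal(f1$amplitudes, 1.0, tolerance = 1e-6)
  expect_error(fit_monoexp(tac("x", c(1, 2), c(1, 0.5))), "at least 3")
  expect_error(fit_monoexp(tac("x", c(1, 2, 3), c(1, 0, 0.5))), "positive")
})

test_that("a near-constant curve is flagged at the rate bound", {
  x <- tac("x", c(0.5, 3, 24, 48, 72), rep(0.8, 5))
  expect_warning(f <- fit_monoexp(x), "lower bound")
  expect_true(f$at_bound)
  # bounded at the physical decay constant
  expect_equal(f$rates[1], decay_constant(159.53), tolerance = 1e-6)
})

test_that("biexponential fit recovers noiseless parameters to 4 figures", {
  times <- c(0.5, 3, 24, 48, 72, 168)
  lam <- log(2) / c(10, 100)
  x <- tac("x", times, 0.5 * exp(-lam[1] * times) + 0.5 * exp(-lam[2] * times))
  f <- fit_biexp(x, min_rate = 0)
  expect_equal(f$model, "bi")
  expect_equal(f$amplitudes, c(0.5, 0.5), tolerance = 1e-4)
  expect_equal(log(2) / f$rates, c(10, 100), tolerance = 1e-4)
  expect_gt(f$rates[1], f$rates[2])  # fast-to-slow convention
  expect_error(fit_biexp(tac("x", 1:4, exp(-0.1 * (1:4)))), "at least 5")
})

test_that("monoexponential data collapse the biexponential model", {
  x <- make_mono_tac(t_eff = 40)
  f <- suppressWarnings(fit_biexp(x))
  # either the rates collapsed (mono fallback) or one amplitude vanished
  if (f$model == "mono") {
    expect_equal(f$effective_half_life, 40, tolerance = 1e-4)
  } else {
    expect_lt(min(f$amplitudes) / max(f$amplitudes), 1e-3)
  }
})

test_that("corrected-AIC selection prefers the true model", {
  times <- c(0.5, 3, 24, 48, 72, 168)
  lam <- log(2) / c(8, 90)
  xb <- tac("x", times, 0.6 * exp(-lam[1] * times) + 0.4 * exp(-lam[2] * times))
  mono <- fit_monoexp(xb, min_rate = 0)
  bi <- fit_biexp(xb, min_rate = 0)
  expect_equal(select_model(mono, bi)$model, "bi")
  # mono truth: parsimony tie rule
  xm <- make_mono_tac(t_eff = 40)
  mono2 <- fit_monoexp(xm, min_rate = 0)
  bi2 <- suppressWarnings(fit_biexp(xm, min_rate = 0))
  expect_equal(select_model(mono2, bi2)$model, "mono")
  # identical rss goes to mono
  f1 <- tac_fit("x", "mono", 1, 0.02, rss = 0.5, n_points = 6)
  f2 <- tac_fit("x", "bi", c(0.5, 0.5), c(0.1, 0.01), rss = 0.5, n_points = 6)
  expect_equal(select_model(f1, f2)$model, "mono")
  f3 <- tac_fit("x", "bi", c(0.5, 0.5), c(0.1, 0.01), rss = 0.5, n_points = 7)
  expect_error(select_model(f1, f3), "n_points")
})

test_that("TIAC is the analytic integral of the fitted model", {
  f <- tac_fit("x", "mono", 1.0, log(2) / 35, rss = 0, n_points = 6)
  expect_equal(tiac(f), 50.49, tolerance = 1e-3)
  fb <- tac_fit("x", "bi", c(0.5, 0.5), log(2) / c(10, 100), rss = 0,
                n_points = 6)
  expect_equal(tiac(fb), 79.35, tolerance = 1e-3)
  f0 <- tac_fit("x", "mono", 0, 0.01, rss = 0, n_points = 6)
  expect_equal(tiac(f0), 0)
})

test_that("TIAC matches numerical integration within 0.1%", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(1:2, 1)
    a <- runif(k, 0.05, 1)
    lam <- log(2) / runif(k, 5, 150)
    f <- tac_fit("x", if (k == 1) "mono" else "bi", a, lam, rss = 0,
                 n_points = 6)
    expect_equal(tiac(f), tiac_numeric(a, lam), tolerance = 1e-3)
  }
})

test_that("effective half-life uses the TIAC-equivalent convention", {
  f <- tac_fit("x", "mono", 1, log(2) / 35, rss = 0, n_points = 5)
  expect_equal(f$effective_half_life, 35)
  fb <- tac_fit("x", "bi", c(0.5, 0.5), log(2) / c(10, 100), rss = 0,
                n_points = 6)
  expect_equal(fb$effective_half_life, 55, tolerance = 1e-3)
  # vanishing second component reduces to the mono value
  fb0 <- tac_fit("x", "bi", c(0.7, 0), log(2) / c(25, 100), rss = 0,
                 n_points = 6)
  expect_equal(fb0$effective_half_life, 25, tolerance = 1e-10)
  expect_error(tac_fit("x", "mono", 1, -0.1, 0, 5), "> 0")
})

test_that("fitted half-life never exceeds the physical one when decay is included", {
  set.seed(7)
  t_phys <- 159.53
  for (te in runif(10, 20, 159)) {
    x <- make_mono_tac(t_eff = te)  # includes physical decay by construction
    f <- fit_monoexp(x)
    expect_lte(f$effective_half_life, t_phys + 1e-6)
  }
  # even a physically impossible slow curve is clamped at the physical rate
  x_slow <- make_mono_tac(t_eff = 400)
  f <- suppressWarnings(fit_monoexp(x_slow))
  expect_lte(f$effective_half_life, t_phys + 1e-6)
})

test_that("fit results serialize to JSON", {
  fits <- list(whole_body = fit_monoexp(make_mono_tac(t_eff = 35)))
  path <- withr::local_tempfile(fileext = ".json")
  write_fits_json(fits, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$whole_body$model, "mono")
  expect_equal(back$whole_body$tiac_h, 50.49, tolerance = 1e-3)
})
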