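# Mono-/biexponential TAC fitting, model selection, effective half-life, TIAC.

#' Construct a fit result
#'
#' Container for a fitted retention model `sum_j a_j exp(-lambda_j t)`. Rates
#' are effective (biological + physical combined, because the fitted data
#' include physical decay). Not normally called by users; [fit_monoexp()] and
#' [fit_biexp()] return these.
#'
#' @param region Region label.
#' @param model `"mono"` or `"bi"`.
#' @param amplitudes Non-negative amplitudes (fractions of injected activity;
#'   per liter for blood curves).
#' @param rates Positive effective decay rates, 1/h; for `"bi"` ordered fast
#'   to slow.
#' @param rss Residual sum of squares of the fit.
#' @param n_points Number of fitted samples.
#' @param at_bound Logical flag: some rate sits on the lower optimization
#'   bound (e.g. a near-constant curve clamped at the physical decay rate).
#' @param se Optional named standard errors of the fitted parameters.
#' @return Object of class `tac_fit` with fields including `effective_half_life`
#'   (hours) and `tiac` (hours, `sum(a_j / lambda_j)`).
#' @export
tac_fit <- function(region, model, amplitudes, rates, rss, n_points,
                    at_bound = FALSE, se = NULL) {
  model <- match.arg(model, c("mono", "bi"))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (any(rates <= 0)) stop("rates must be > 0")
  if (length(amplitudes) != length(rates)) stop("amplitude/rate length mismatch")
  o <- order(rates, decreasing = TRUE)
  amplitudes <- amplitudes[o]; rates <- rates[o]
  fit <- structure(
    list(region = region, model = model, amplitudes = amplitudes,
         rates = rates, rss = rss, n_points = as.integer(n_points),
         at_bound = isTRUE(at_bound), se = se),
    class = "tac_fit")
  fit$tiac <- tiac(fit)
  fit$effective_half_life <- if (sum(amplitudes) > 0) effective_half_life(fit)
                             else NA_real_
  fit
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit %s, %s> T_eff = %.2f h, TIAC = %.3f h, rss = %.3g (n = %d)\n",
              x$region, x$model, x$effective_half_life, x$tiac, x$rss,
              x$n_points))
  invisible(x)
}

# log-linear least squares on (t, v): slope gives a starting rate, intercept a
# starting amplitude
.loglin_start <- function(t, v) {
  co <- stats::coef(stats::lm(log(v) ~ t))
  list(a = exp(unname(co[1])), lambda = max(-unname(co[2]), 1e-8))
}

#' Fit a monoexponential retention function
#'
#' Unweighted least squares of `a exp(-lambda t)` in linear space
#' (Levenberg-Marquardt), initialized from a log-linear regression. The rate
#' is bounded below by `min_rate` (default: the physical decay constant of
#' `nuclide`, since measured activity cannot decline slower than physical
#' decay); a fit landing on that bound is flagged `at_bound`.
#'
#' @param x A [tac()] with at least 3 strictly positive samples.
#' @param nuclide `radionuclide` supplying the default lower rate bound.
#' @param min_rate Lower bound for the decay rate, 1/h; set 0 to disable.
#' @return A [tac_fit()].
#' @export
fit_monoexp <- function(x, nuclide = lu177(),
                        min_rate = decay_constant(nuclide$physical_half_life)) {
  stopifnot(inherits(x, "tac"))
  if (length(x$time_h) < 3)
    stop("monoexponential fit needs at least 3 samples")
  if (any(x$fia <= 0))
    stop("monoexponential fit needs strictly positive values")
  t <- x$time_h; v <- x$fia
  s <- .loglin_start(t, v)
  fit <- minpack.lm::nlsLM(
    v ~ a * exp(-lambda * t),
    start = list(a = s$a, lambda = max(s$lambda, min_rate)),
    lower = c(a = 0, lambda = min_rate),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- stats::coef(fit)
  at_bound <- min_rate > 0 && (p["lambda"] - min_rate) < 1e-10
  if (at_bound)
    warning("fitted rate sits on the lower bound (near-constant curve)")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  tac_fit(x$region, "mono", unname(p["a"]), unname(p["lambda"]),
          sum(stats::resid(fit)^2), length(t), at_bound, se = se)
}

#' Fit a biexponential retention function
#'
#' Least squares of `a1 exp(-l1 t) + a2 exp(-l2 t)` with `l1 > l2` by
#' convention. Starting values: the slow component from a log-linear fit to
#' the tail, the fast component from the early residual. If the two rates
#' collapse onto each other the model is degenerate and the monoexponential
#' fit is returned instead, with a warning.
#'
#' @param x A [tac()] with at least 5 strictly positive samples.
#' @inheritParams fit_monoexp
#' @return A [tac_fit()] (model `"bi"`, or `"mono"` on rate collapse).
#' @export
fit_biexp <- function(x, nuclide = lu177(),
                      min_rate = decay_constant(nuclide$physical_half_life)) {
  stopifnot(inherits(x, "tac"))
  if (length(x$time_h) < 5)
    stop("biexponential fit needs at least 5 samples")
  if (any(x$fia <= 0))
    stop("biexponential fit needs strictly positive values")
  t <- x$time_h; v <- x$fia
  n <- length(t)
  tail_idx <- max(n - 2, ceiling(n / 2)):n
  slow <- .loglin_start(t[tail_idx], v[tail_idx])
  resid_early <- v - slow$a * exp(-max(slow$lambda, min_rate) * t)
  early_idx <- which(resid_early > 0 & seq_len(n) <= ceiling(n / 2))
  if (length(early_idx) >= 2) {
    fast <- .loglin_start(t[early_idx], resid_early[early_idx])
  } else {
    fast <- list(a = v[1] / 2, lambda = 5 * max(slow$lambda, min_rate))
  }
  start <- list(a1 = max(fast$a, 1e-6), l1 = max(fast$lambda, 2 * min_rate, 1e-6),
                a2 = max(slow$a, 1e-6), l2 = max(slow$lambda, min_rate))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ a1 * exp(-l1 * t) + a2 * exp(-l2 * t),
      start = start,
      lower = c(a1 = 0, l1 = min_rate, a2 = 0, l2 = min_rate),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("biexponential fit failed to converge; falling back to monoexponential")
    return(fit_monoexp(x, nuclide, min_rate))
  }
  p <- stats::coef(fit)
  rates <- sort(c(p["l1"], p["l2"]), decreasing = TRUE)
  if ((rates[1] - rates[2]) / rates[1] < 1e-3) {
    warning("biexponential rates collapsed; falling back to monoexponential")
    return(fit_monoexp(x, nuclide, min_rate))
  }
  at_bound <- min_rate > 0 && any(c(p["l1"], p["l2"]) - min_rate < 1e-10)
  tac_fit(x$region, "bi", unname(p[c("a1", "a2")]), unname(p[c("l1", "l2")]),
          sum(stats::resid(fit)^2), n, at_bound)
}

#' Select between the mono- and biexponential fit
#'
#' Corrected AIC from the residual sum of squares,
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n-k-1)` with k the number of fitted
#' parameters (2 or 4). Ties, and the degenerate case where both fits are
#' numerically exact, go to the monoexponential model (parsimony).
#'
#' @param mono,bi [tac_fit()] objects fitted to the same data.
#' @return The selected [tac_fit()].
#' @export
select_model <- function(mono, bi) {
  stopifnot(inherits(mono, "tac_fit"), inherits(bi, "tac_fit"))
  if (mono$n_points != bi$n_points)
    stop("fits were not computed on the same data (n_points differ)")
  if (bi$model == "mono") return(mono)  # bi collapsed during fitting
  n <- mono$n_points
  both_exact <- max(mono$rss, bi$rss) < 1e-20
  if (both_exact) return(mono)
  aicc <- function(rss, k) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  if (aicc(bi$rss, 4) < aicc(mono$rss, 2)) bi else mono
}

#' Time-integrated activity coefficient
#'
#' Analytic integral of the fitted curve from 0 to infinity,
#' `sum_j a_j / lambda_j`, in hours: the number of decays in the region per
#' unit administered activity, divided by the administered activity's decay
#' rate units (h).
#'
#' @param fit A [tac_fit()].
#' @return TIAC in hours.
#' @export
tiac <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  sum(fit$amplitudes / fit$rates)
}

#' Effective half-life of a fitted curve
#'
#' Monoexponential: `ln(2)/lambda`. Biexponential: the TIAC-equivalent single
#' half-life `ln(2) * TIAC / sum(a_j)`, i.e. the half-life of the
#' monoexponential curve with the same initial amplitude and the same
#' integral.
#'
#' @param fit A [tac_fit()].
#' @return Effective half-life in hours.
#' @export
effective_half_life <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  a0 <- sum(fit$amplitudes)
  if (a0 <= 0) stop("total amplitude is zero: effective half-life undefined")
  if (fit$model == "mono") log(2) / fit$rates[1]
  else log(2) * tiac(fit) / a0
}

#' Serialize fit results to JSON
#'
#' One record per region: model, amplitudes, rates, effective half-life,
#' TIAC, rss, n_points.
#'
#' @param fits Named list of [tac_fit()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  rec <- lapply(fits, function(f)
    list(region = f$region, model = f$model, amplitudes = f$amplitudes,
         rates_per_h = f$rates, effective_half_life_h = f$effective_half_life,
         tiac_h = f$tiac, rss = f$rss, n_points = f$n_points))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
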