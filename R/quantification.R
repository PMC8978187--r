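# Conjugate-view planar quantification and hybrid SPECT rescaling.

#' Time-activity curve
#'
#' A region's activity over time as a fraction of injected activity.
#'
#' @param region Region label.
#' @param time_h Sample times in hours, strictly increasing.
#' @param fia Fractions of injected activity, non-negative. For blood curves
#'   the values are fractions of injected activity per liter.
#' @param provenance One of `"planar"`, `"planar_spect_scaled"`, `"blood"`.
#' @return An object of class `tac`.
#' @export
tac <- function(region, time_h, fia,
                provenance = c("planar", "planar_spect_scaled", "blood")) {
  provenance <- match.arg(provenance)
  if (length(time_h) != length(fia)) stop("time_h and fia lengths differ")
  if (length(time_h) > 1 && is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(fia < 0)) stop("fractions of injected activity must be >= 0")
  structure(list(region = region, time_h = as.numeric(time_h),
                 fia = as.numeric(fia), provenance = provenance),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac %s, %s, %d samples over %.1f-%.1f h>\n", x$region,
              x$provenance, length(x$time_h), min(x$time_h), max(x$time_h)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(region = x$region, time_h = x$time_h, fia = x$fia,
             provenance = x$provenance)
}

#' Conjugate-view attenuation-corrected counts
#'
#' Geometric mean of the anterior/posterior pair divided by the square root of
#' the body transmission factor at the region
#' (`T = exp(-mu * thickness)`), the standard MIRD Pamphlet 16 form:
#' `sqrt(N_ant N_post / T)`.
#'
#' @param anterior,posterior Counts (>= 0).
#' @param transmission Transmission factor in (0, 1]; 1 applies no attenuation
#'   correction beyond the geometric mean.
#' @return Attenuation-corrected counts.
#' @export
conjugate_view_counts <- function(anterior, posterior, transmission = 1) {
  anterior <- as.numeric(anterior)    # counts may arrive as 32-bit integers;
  posterior <- as.numeric(posterior)  # their product must not overflow
  if (any(anterior < 0) || any(posterior < 0)) stop("counts must be >= 0")
  if (any(transmission <= 0) || any(transmission > 1))
    stop("transmission must lie in (0, 1]")
  sqrt(anterior * posterior) / sqrt(transmission)
}

#' Normalize a planar series to fractions of injected activity
#'
#' Applies conjugate-view correction to every (region, time) pair and divides
#' by the corrected whole-body counts of the earliest scan, which are defined
#' to be 100% of the administered activity (the patient has not voided before
#' the first scan). The whole-body curve therefore starts at exactly 1.
#'
#' @param scans Data frame as produced by [simulate_planar_series()]: columns
#'   `region`, `time_h`, `anterior_counts`, `posterior_counts` and optionally
#'   `thickness_cm`.
#' @param transmission Per-region transmission factors: a named vector, a
#'   single number recycled to all regions, or `NULL` (default) to use 1
#'   everywhere unless `attenuation_mu` is given.
#' @param attenuation_mu If supplied together with a `thickness_cm` column,
#'   transmission is computed as `exp(-mu * thickness)` per row.
#' @return Named list of [tac()] objects, one per region, provenance
#'   `"planar"`.
#' @export
normalize_series <- function(scans, transmission = NULL, attenuation_mu = NULL) {
  req <- c("region", "time_h", "anterior_counts", "posterior_counts")
  if (!all(req %in% names(scans))) stop("scans is missing required columns")
  if (!"whole_body" %in% scans$region)
    stop("whole-body region must be present on every scan")
  if (!is.null(attenuation_mu)) {
    if (!"thickness_cm" %in% names(scans))
      stop("attenuation_mu requires a thickness_cm column")
    trans <- exp(-attenuation_mu * scans$thickness_cm)
  } else if (is.null(transmission)) {
    trans <- rep(1, nrow(scans))
  } else if (!is.null(names(transmission))) {
    trans <- transmission[scans$region]
    if (any(is.na(trans))) stop("transmission missing for some regions")
  } else {
    trans <- rep(transmission, length.out = nrow(scans))
  }
  corrected <- conjugate_view_counts(scans$anterior_counts,
                                     scans$posterior_counts, trans)
  t0 <- min(scans$time_h)
  wb0 <- corrected[scans$region == "whole_body" & scans$time_h == t0]
  if (length(wb0) != 1) stop("whole-body region must appear exactly once per scan")
  if (wb0 <= 0) stop("zero whole-body counts on the first scan: cannot normalize")
  out <- lapply(split(seq_len(nrow(scans)), scans$region), function(idx) {
    o <- idx[order(scans$time_h[idx])]
    tac(scans$region[o[1]], scans$time_h[o], corrected[o] / wb0, "planar")
  })
  out[unique(scans$region)]
}

#' Log-linear interpolation of a time-activity curve
#'
#' Activity between samples is assumed to decay exponentially, so
#' interpolation is linear in `log(fia)` vs time.
#'
#' @param x A [tac()].
#' @param t Time in hours; must lie within the sampled span.
#' @return Interpolated fraction of injected activity.
#' @export
interpolate_tac <- function(x, t) {
  stopifnot(inherits(x, "tac"))
  if (t < min(x$time_h) || t > max(x$time_h))
    stop("time outside the sampled span: refusing to extrapolate")
  if (any(x$fia <= 0))
    stop("log-linear interpolation requires strictly positive values")
  exp(stats::approx(x$time_h, log(x$fia), xout = t)$y)
}

#' Rescale a planar time-activity curve with the SPECT measurement
#'
#' The quantitative SPECT activity of a source region anchors the shape-only
#' planar curve: every value is multiplied by
#' `k = (A_spect / administered) / FIA_planar(t_spect)`, where the planar
#' fraction at the SPECT time comes from log-linear interpolation. The scaled
#' curve passes exactly through the SPECT point.
#'
#' @param x A [tac()] with planar provenance.
#' @param spect_activity Measured SPECT activity, MBq (> 0).
#' @param spect_time Measurement time, hours; must lie within the curve span.
#' @param administered Administered activity, GBq (> 0).
#' @return A [tac()] with provenance `"planar_spect_scaled"`.
#' @export
scale_tac_by_spect <- function(x, spect_activity, spect_time, administered) {
  stopifnot(inherits(x, "tac"))
  if (length(x$time_h) == 0) stop("empty time-activity curve")
  if (administered <= 0) stop("administered activity must be > 0 GBq")
  if (spect_activity <= 0) stop("SPECT activity must be > 0 MBq")
  if (x$region == "whole_body")
    stop("the whole-body curve is never SPECT-scaled (regional field of view)")
  planar_fia <- interpolate_tac(x, spect_time)
  if (planar_fia <= 0) stop("planar fraction at the SPECT time is zero")
  k <- (spect_activity / 1000 / administered) / planar_fia
  tac(x$region, x$time_h, x$fia * k, "planar_spect_scaled")
}

#' Write / read time-activity curves as tidy CSV
#'
#' Columns: `region`, `time_h`, `fia`, `provenance`. The reader validates
#' strictly increasing times within each region.
#'
#' @param tacs Named list of [tac()] objects.
#' @param path CSV path.
#' @return `write_tac_csv` the path, invisibly; `read_tac_csv` a named list of
#'   [tac()] objects.
#' @export
write_tac_csv <- function(tacs, path) {
  df <- do.call(rbind, lapply(tacs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$time_h), ]
    tac(d$region[1], d$time_h, d$fia, d$provenance[1])
  })
  out[unique(df$region)]
}
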