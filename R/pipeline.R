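# End-to-end orchestration: screening, per-cycle dosimetry, cohort summary.

#' Screen a patient by tumor-to-liver SUV ratio
#'
#' Eligibility on the pretherapeutic PET: significant target expression is
#' required, defined as a tumor-to-background (liver) SUV ratio strictly
#' greater than 3.
#'
#' @param suv_tumor Tumor SUV (>= 0).
#' @param suv_liver Liver (background) SUV (> 0).
#' @return List with `ratio` and logical `eligible`.
#' @export
screen_eligibility <- function(suv_tumor, suv_liver) {
  if (suv_liver <= 0) stop("liver SUV must be > 0")
  if (suv_tumor < 0) stop("tumor SUV must be >= 0")
  ratio <- suv_tumor / suv_liver
  list(ratio = ratio, eligible = ratio > 3)
}

.is_lesion <- function(region) grepl("metastasis|lesion|tumor", region)

#' Run the full dosimetry chain for one treatment cycle
#'
#' Planar normalization, SPECT rescaling of source-region curves, mono-/
#' biexponential fitting with corrected-AIC selection, and absorbed doses:
#' whole body and organs by the mass-adapted self-dose (photon absorbed
#' fraction from the sphere parameterization at the region mass), lesions
#' (regions matching `metastasis|lesion|tumor`) by the unit-density sphere
#' model, and red marrow from blood samples when supplied, otherwise from the
#' whole-body distribution.
#'
#' @param scans Planar series data frame (see [simulate_planar_series()] /
#'   real-data CSV with the same columns); at least 5 scan times and a
#'   `whole_body` region are required.
#' @param administered Administered activity, GBq.
#' @param region_masses Named vector of region masses in kg.
#' @param spect Optional data frame `region`, `time_h`, `activity_mbq` with
#'   one quantitative SPECT measurement per source region.
#' @param blood Optional data frame `time_h`, `fia_per_l` of blood samples.
#' @param transmission,attenuation_mu Passed to [normalize_series()].
#' @param nuclide A `radionuclide` (default [lu177()]).
#' @param phantom [phantom_masses()] list.
#' @param rmblr Red-marrow-to-blood concentration ratio for the blood method.
#' @return List with `tacs` (named list of [tac()]), `fits` (named list of
#'   [tac_fit()]), `doses` (data frame of [dose_result()] rows) and
#'   `marrow_method`.
#' @export
run_patient_dosimetry <- function(scans, administered, region_masses,
                                  spect = NULL, blood = NULL,
                                  transmission = NULL, attenuation_mu = NULL,
                                  nuclide = lu177(),
                                  phantom = phantom_masses(), rmblr = 1) {
  if (length(unique(scans$time_h)) < 5)
    stop("the dosimetry protocol requires at least 5 planar scan times")
  if (!"whole_body" %in% scans$region)
    stop("whole-body region is required for normalization")
  tacs <- normalize_series(scans, transmission = transmission,
                           attenuation_mu = attenuation_mu)
  if (!is.null(spect)) {
    for (i in seq_len(nrow(spect))) {
      r <- spect$region[i]
      if (is.null(tacs[[r]]) || r == "whole_body") next
      tacs[[r]] <- scale_tac_by_spect(tacs[[r]], spect$activity_mbq[i],
                                      spect$time_h[i], administered)
    }
  }
  fits <- list()
  for (r in names(tacs)) {
    fits[[r]] <- tryCatch({
      mono <- fit_monoexp(tacs[[r]], nuclide)
      if (length(tacs[[r]]$time_h) >= 5) {
        bi <- suppressWarnings(fit_biexp(tacs[[r]], nuclide))
        select_model(mono, bi)
      } else mono
    }, error = function(e) {
      warning(sprintf("region %s not fitted: %s", r, conditionMessage(e)))
      NULL
    })
  }
  fits <- Filter(Negate(is.null), fits)
  if (is.null(fits$whole_body))
    stop("whole-body curve could not be fitted")
  doses <- list()
  for (r in names(fits)) {
    f <- fits[[r]]
    m <- region_masses[[r]]
    if (is.null(m) || is.na(m)) {
      warning("no mass for region ", r, ": dose skipped")
      next
    }
    doses[[r]] <- if (.is_lesion(r)) {
      dose_result(r, sphere_dose(tiac(f), m * 1000, nuclide), tiac(f), m,
                  "sphere")
    } else {
      phi <- photon_absorbed_fraction_sphere(m * 1000)
      dose_result(r, self_absorbed_dose(tiac(f), m, nuclide, phi), tiac(f), m,
                  "organ_self")
    }
  }
  marrow_method <- if (!is.null(blood) && nrow(blood) > 0) "marrow_blood"
                   else "marrow_wholebody"
  doses$red_marrow <- if (marrow_method == "marrow_blood") {
    marrow_dose_blood(tac("blood", blood$time_h, blood$fia_per_l, "blood"),
                      phantom, rmblr, nuclide)
  } else {
    marrow_dose_wholebody(fits$whole_body, phantom, nuclide)
  }
  doses_df <- do.call(rbind, unname(doses))
  rownames(doses_df) <- NULL
  list(tacs = tacs, fits = fits, doses = doses_df,
       marrow_method = marrow_method)
}

#' Cohort summary statistics
#'
#' Mean, sample standard deviation (n-1 denominator), minimum, maximum and n
#' of effective half-life and absorbed dose per region across treatment
#' cycles (the cohort unit is the cycle). With a single cycle the SD is `NA`.
#'
#' @param reports List of results from [run_patient_dosimetry()].
#' @return Data frame: `region`, `quantity` (`t_eff_h` | `dose_gy_per_gbq`),
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @export
cohort_summary <- function(reports) {
  if (length(reports) == 0) stop("empty cohort")
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rep <- reports[[i]]
    d <- rep$doses
    te <- vapply(d$region, function(r) {
      if (!is.null(rep$fits[[r]])) rep$fits[[r]]$effective_half_life
      else NA_real_  # blood-method marrow has no region fit
    }, 0)
    data.frame(cycle = i, region = d$region, t_eff_h = unname(te),
               dose_gy_per_gbq = d$absorbed_dose_gy_per_gbq,
               stringsAsFactors = FALSE)
  }))
  # pool lesions of the same type across cycles (bone_metastasis_1/2 -> bone_metastasis)
  rows$group <- sub("_[0-9]+$", "", rows$region)
  long <- rbind(
    data.frame(region = rows$group, quantity = "t_eff_h", value = rows$t_eff_h),
    data.frame(region = rows$group, quantity = "dose_gy_per_gbq",
               value = rows$dose_gy_per_gbq))
  long <- long[!is.na(long$value), ]
  out <- do.call(rbind, lapply(split(long, list(long$region, long$quantity),
                                     drop = TRUE), function(g) {
    data.frame(region = g$region[1], quantity = g$quantity[1],
               mean = mean(g$value),
               sd = if (nrow(g) > 1) stats::sd(g$value) else NA_real_,
               min = min(g$value), max = max(g$value), n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$quantity, out$region), ]
}

#' Format a cohort summary as the conventional text table
#'
#' One line per region and quantity, `mean +/- SD (range, min-max)`, doses to
#' 2 decimals and half-lives to the nearest hour.
#'
#' @param summary Data frame from [cohort_summary()].
#' @return Character vector of formatted lines.
#' @export
format_cohort_summary <- function(summary) {
  fmt <- function(v, digits) formatC(v, format = "f", digits = digits)
  vapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    dg <- if (s$quantity == "t_eff_h") 0 else 2
    unit <- if (s$quantity == "t_eff_h") "h" else "Gy/GBq"
    sprintf("%s %s: %s +/- %s %s (range, %s-%s; n = %d)",
            s$region, s$quantity, fmt(s$mean, dg),
            if (is.na(s$sd)) "NA" else fmt(s$sd, dg), unit,
            fmt(s$min, dg), fmt(s$max, dg), s$n)
  }, "")
}

#' Write dose-report rows as CSV
#'
#' Columns mirror the per-cycle supplemental-table layout: region, effective
#' half-life, TIAC, absorbed dose, method. The whole-body row is labeled as
#' absorbed (not Sv-weighted effective) dose.
#'
#' @param report Result of [run_patient_dosimetry()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_dose_csv <- function(report, path) {
  d <- report$doses
  te <- vapply(d$region, function(r) {
    if (!is.null(report$fits[[r]])) report$fits[[r]]$effective_half_life
    else NA_real_
  }, 0)
  out <- data.frame(region = d$region, t_eff_h = unname(te),
                    tiac_h = d$tiac_h,
                    absorbed_dose_gy_per_gbq = d$absorbed_dose_gy_per_gbq,
                    method = d$method)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
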