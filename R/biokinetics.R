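# Virtual-patient simulator: region kinetics, planar scans, SPECT, blood.

#' Per-region retention kinetics
#'
#' Retention of a region as a sum of one (monoexponential) or two
#' (biexponential) decaying terms. Amplitudes are fractions of injected
#' activity present in the region at t = 0; half-lives are *biological*
#' (physical decay is applied separately when the curve is evaluated).
#' Rising (uptake-phase) curves are not modeled.
#'
#' @param region Region label, e.g. `"whole_body"`, `"kidneys"`,
#'   `"bone_metastasis_1"`, `"blood"`.
#' @param amplitudes Numeric vector (length 1 or 2) of non-negative fractions
#'   of injected activity.
#' @param biological_half_lives Matching vector of biological half-lives in
#'   hours; `Inf` means no biological clearance of that term.
#' @return An object of class `region_kinetics`.
#' @export
region_kinetics <- function(region, amplitudes, biological_half_lives) {
  stopifnot(is.character(region), length(region) == 1)
  if (length(amplitudes) != length(biological_half_lives))
    stop("amplitudes and biological_half_lives must have equal length")
  if (length(amplitudes) < 1 || length(amplitudes) > 2)
    stop("kinetics must have 1 (mono) or 2 (bi) exponential terms")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (any(biological_half_lives <= 0)) stop("biological half-lives must be > 0")
  structure(
    list(region = region, amplitudes = as.numeric(amplitudes),
         biological_half_lives = as.numeric(biological_half_lives)),
    class = "region_kinetics"
  )
}

#' Virtual patient
#'
#' A synthetic treatment cycle: administered activity, per-region retention
#' kinetics, region masses, and per-region body thickness for conjugate-view
#' attenuation. Source-region amplitudes (everything except `whole_body` and
#' `blood`, which overlap the rest of the body) may not sum past the
#' whole-body amplitude.
#'
#' @param administered_activity Administered activity in GBq (> 0).
#' @param kinetics List of [region_kinetics()] objects; must include
#'   `whole_body`.
#' @param region_masses Named numeric vector of region masses in kg (tumor
#'   spheres included: a 10-g lesion is 0.010 kg). Every kinetic region except
#'   `blood` needs a mass.
#' @param body_thickness Named numeric vector of patient thickness in cm at
#'   each region (for planar attenuation), or a single number recycled to all
#'   regions. Default 20 cm.
#' @param nuclide A `radionuclide`; default [lu177()].
#' @param blood_volume_l Blood volume in liters (default 5).
#' @return An object of class `virtual_patient`.
#' @export
virtual_patient <- function(administered_activity, kinetics, region_masses,
                            body_thickness = 20, nuclide = lu177(),
                            blood_volume_l = 5) {
  if (!is.finite(administered_activity) || administered_activity <= 0)
    stop("administered_activity must be positive (GBq)")
  stopifnot(is.list(kinetics), all(vapply(kinetics, inherits, TRUE, "region_kinetics")))
  names(kinetics) <- vapply(kinetics, `[[`, "", "region")
  if (!"whole_body" %in% names(kinetics))
    stop("kinetics must include a whole_body region")
  needs_mass <- setdiff(names(kinetics), "blood")
  missing_mass <- setdiff(needs_mass, names(region_masses))
  if (length(missing_mass) > 0)
    stop("missing region mass for: ", paste(missing_mass, collapse = ", "))
  if (any(region_masses <= 0)) stop("region masses must be > 0")
  src <- setdiff(names(kinetics), c("whole_body", "blood"))
  a_src <- sum(vapply(kinetics[src], function(k) sum(k$amplitudes), 0))
  a_wb <- sum(kinetics$whole_body$amplitudes)
  if (a_src > a_wb + 1e-12)
    stop("source-region amplitudes exceed the whole-body amplitude")
  if (length(body_thickness) == 1 && is.null(names(body_thickness)))
    body_thickness <- stats::setNames(rep(body_thickness, length(needs_mass)), needs_mass)
  if (any(body_thickness < 0)) stop("body thickness must be non-negative")
  structure(
    list(administered_activity = administered_activity,
         kinetics = kinetics,
         region_masses = region_masses,
         body_thickness = body_thickness,
         nuclide = nuclide,
         blood_volume_l = blood_volume_l),
    class = "virtual_patient"
  )
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("<virtual_patient> %.2f GBq %s, regions: %s\n",
              x$administered_activity, x$nuclide$name,
              paste(names(x$kinetics), collapse = ", ")))
  invisible(x)
}

#' Planar acquisition protocol
#'
#' The serial-imaging schedule and camera model. Defaults follow the
#' mandatory clinical schedule (immediately after injection, 2-3 h, and 1, 2
#' and 3 d) plus an optional delayed scan at 7 d.
#'
#' @param scan_times Planar scan times, hours post injection; must be strictly
#'   increasing, start at or before 1 h, and contain at least 5 points.
#' @param spect_time Time of the single quantitative SPECT, hours.
#' @param spect_regions Regions covered by the SPECT field of view.
#' @param blood_times Venous sampling times in hours (empty = no samples).
#' @param linear_attenuation Effective linear attenuation coefficient, 1/cm
#'   (default 0.11 for the 208-keV Lu-177 photopeak in soft tissue).
#' @param camera_sensitivity Planar system sensitivity, counts per (MBq min).
#' @param scan_duration Effective acquisition time per region, minutes.
#' @param noise Logical: draw Poisson counts (`TRUE`) or return expected
#'   counts (`FALSE`).
#' @param seed Integer seed used for the Poisson draws.
#' @param spect_calibration Multiplicative SPECT calibration factor (1 =
#'   perfectly calibrated; other values exercise the hybrid scaling step).
#' @param background_rate Uniform background count rate added to each ROI,
#'   counts per minute (default 0, i.e. no background term).
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(scan_times = c(0.5, 3, 24, 48, 72, 168),
                                 spect_time = 24,
                                 spect_regions = c("kidneys"),
                                 blood_times = numeric(0),
                                 linear_attenuation = 0.11,
                                 camera_sensitivity = 600,
                                 scan_duration = 15,
                                 noise = TRUE,
                                 seed = 1L,
                                 spect_calibration = 1.0,
                                 background_rate = 0) {
  if (is.unsorted(scan_times, strictly = TRUE))
    stop("scan_times must be strictly increasing")
  if (scan_times[1] > 1)
    stop("the first scan must be acquired within 1 h of injection")
  if (length(scan_times) < 5)
    stop("at least 5 planar scans are required")
  if (linear_attenuation < 0 || camera_sensitivity <= 0 || scan_duration <= 0)
    stop("invalid camera parameters")
  structure(
    list(scan_times = scan_times, spect_time = spect_time,
         spect_regions = spect_regions, blood_times = blood_times,
         linear_attenuation = linear_attenuation,
         camera_sensitivity = camera_sensitivity,
         scan_duration = scan_duration, noise = isTRUE(noise),
         seed = as.integer(seed), spect_calibration = spect_calibration,
         background_rate = background_rate),
    class = "acquisition_protocol"
  )
}

#' True regional activity as a fraction of injected activity
#'
#' Evaluates the region's retention function including physical decay:
#' `sum_j a_j exp(-(lambda_bio_j + lambda_phys) t)`.
#'
#' @param patient A `virtual_patient`.
#' @param region Region label present on the patient.
#' @param t Time(s) post injection, hours (>= 0).
#' @return Fraction(s) of injected activity.
#' @export
region_activity <- function(patient, region, t) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (any(t < 0)) stop("t must be >= 0")
  k <- patient$kinetics[[region]]
  if (is.null(k)) stop("unknown region: ", region)
  lam_phys <- decay_constant(patient$nuclide$physical_half_life)
  lam <- decay_constant(k$biological_half_lives) + lam_phys
  vapply(t, function(ti) sum(k$amplitudes * exp(-lam * ti)), 0)
}

#' Simulate a serial planar conjugate-view study
#'
#' For every scan time and every planar-visible region (all kinetic regions
#' except `blood`) the expected anterior and posterior counts are
#'
#' `N_ant = A(t) x sensitivity x duration x exp(-mu d)`,
#'
#' with the region placed at mid-depth (`d = thickness/2`) and the posterior
#' path `thickness - d`; so the geometric mean of the noiseless pair is
#' proportional to `A(t) exp(-mu thickness / 2)`. With `noise = TRUE` counts
#' are Poisson-drawn under the protocol seed.
#'
#' @param patient A `virtual_patient`.
#' @param protocol An `acquisition_protocol`.
#' @return A data frame with columns `region`, `time_h`, `anterior_counts`,
#'   `posterior_counts`, `thickness_cm`.
#' @export
simulate_planar_series <- function(patient, protocol) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(protocol, "acquisition_protocol"))
  regions <- setdiff(names(patient$kinetics), "blood")
  grid <- expand.grid(region = regions, time_h = protocol$scan_times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  thick <- patient$body_thickness[grid$region]
  if (any(is.na(thick))) stop("missing body thickness for a planar region")
  if (any(thick < 0)) stop("body thickness must be non-negative")
  act_mbq <- mapply(function(r, t) region_activity(patient, r, t),
                    grid$region, grid$time_h) *
    patient$administered_activity * 1000
  mu <- protocol$linear_attenuation
  d_ant <- thick / 2
  base <- act_mbq * protocol$camera_sensitivity * protocol$scan_duration
  bkg <- protocol$background_rate * protocol$scan_duration
  ant <- base * exp(-mu * d_ant) + bkg
  post <- base * exp(-mu * (thick - d_ant)) + bkg
  if (protocol$noise) {
    withr_seed <- protocol$seed
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(withr_seed)
    ant <- stats::rpois(length(ant), ant)
    post <- stats::rpois(length(post), post)
  }
  data.frame(region = grid$region, time_h = grid$time_h,
             anterior_counts = as.numeric(ant),
             posterior_counts = as.numeric(post),
             thickness_cm = as.numeric(thick),
             row.names = NULL)
}

# save/restore .Random.seed so seeded simulation does not disturb the caller's
# RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate the single quantitative SPECT measurement
#'
#' Returns the true regional activity at the SPECT time multiplied by the
#' protocol's calibration factor (1 = unbiased; e.g. 0.8 models a planar
#' series that over-reads the region by 25%, which the hybrid scaling step
#' must correct).
#'
#' @param patient A `virtual_patient`.
#' @param protocol An `acquisition_protocol`.
#' @param region Region to quantify; must be within `protocol$spect_regions`.
#' @param t Measurement time in hours (default `protocol$spect_time`).
#' @return Measured activity in MBq.
#' @export
simulate_spect <- function(patient, protocol, region, t = protocol$spect_time) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(protocol, "acquisition_protocol"))
  if (!region %in% protocol$spect_regions)
    stop("region not inside the SPECT field of view: ", region)
  fia <- region_activity(patient, region, t)
  fia * patient$administered_activity * 1000 * protocol$spect_calibration
}

#' Simulate venous blood samples
#'
#' Evaluates the patient's blood kinetics at the sampling times and divides by
#' blood volume, yielding an activity concentration in fraction of injected
#' activity per liter.
#'
#' @param patient A `virtual_patient` with a `blood` kinetics entry.
#' @param times Sampling times, hours.
#' @return Data frame with columns `time_h`, `fia_per_l`.
#' @export
simulate_blood_curve <- function(patient, times) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (is.null(patient$kinetics$blood))
    stop("patient has no blood kinetics defined")
  if (length(times) == 0)
    return(data.frame(time_h = numeric(0), fia_per_l = numeric(0)))
  data.frame(time_h = times,
             fia_per_l = region_activity(patient, "blood", times) /
               patient$blood_volume_l)
}
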