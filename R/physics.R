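# Decay constants, half-life algebra and per-decay energy bookkeeping.

.ludosim_env <- new.env(parent = emptyenv())

#' Load the package constants file
#'
#' Reads the versioned YAML file shipped with the package that holds the
#' Lu-177 decay data (ICRP-107), the ICRP-89 reference adult masses, and the
#' unit-density-sphere photon absorbed-fraction parameterization. The parsed
#' list is cached for the session.
#'
#' @param path Optional path to an alternative constants file with the same
#'   structure (useful for overriding decay data).
#' @return A named list with elements `nuclides`, `phantom`, `sphere_phi`.
#' @export
dosimetry_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ludosim_env$constants)) return(.ludosim_env$constants)
    path <- system.file("extdata", "dosimetry_constants.yaml", package = "ludosim")
    cfg <- yaml::read_yaml(path)
    .ludosim_env$constants <- cfg
    return(cfg)
  }
  yaml::read_yaml(path)
}

#' Radionuclide decay data
#'
#' Constructs a radionuclide record: physical half-life and the mean emitted
#' energy per decay split into a locally absorbed electron component
#' (beta + conversion + Auger) and a photon component (gamma + x-ray) whose
#' absorbed share depends on target geometry.
#'
#' @param name Nuclide label.
#' @param physical_half_life Physical half-life in hours (> 0).
#' @param mean_electron_energy Mean electron energy per decay, MeV (>= 0).
#' @param mean_photon_energy Mean photon energy per decay, MeV (>= 0).
#' @return An object of class `radionuclide`.
#' @export
radionuclide <- function(name, physical_half_life, mean_electron_energy,
                         mean_photon_energy) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(physical_half_life) || physical_half_life <= 0)
    stop("physical_half_life must be a positive, finite number of hours")
  if (mean_electron_energy < 0 || mean_photon_energy < 0)
    stop("mean emitted energies must be non-negative")
  structure(
    list(name = name,
         physical_half_life = physical_half_life,
         mean_electron_energy = mean_electron_energy,
         mean_photon_energy = mean_photon_energy),
    class = "radionuclide"
  )
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide %s> T_phys = %.2f h, E_e = %.4f MeV, E_ph = %.4f MeV\n",
              x$name, x$physical_half_life, x$mean_electron_energy,
              x$mean_photon_energy))
  invisible(x)
}

#' Lu-177 decay data
#'
#' The default radionuclide: physical half-life 159.53 h (6.647 d), mean
#' electron energy 0.1479 MeV/decay and mean photon energy 0.0335 MeV/decay
#' (ICRP-107 values, stored in the package constants file).
#'
#' @return A `radionuclide` object.
#' @export
lu177 <- function() {
  n <- dosimetry_constants()$nuclides$lu177
  radionuclide(n$name, n$physical_half_life_h,
               n$mean_electron_energy_mev, n$mean_photon_energy_mev)
}

#' Decay constant from half-life
#'
#' @param half_life Half-life in hours; strictly positive (may be `Inf` for a
#'   non-decaying compartment, giving rate 0).
#' @return Decay rate in 1/h, `ln(2)/half_life`.
#' @export
decay_constant <- function(half_life) {
  if (any(!is.na(half_life) & half_life <= 0))
    stop("half_life must be > 0")
  log(2) / half_life
}

#' Combine biological and physical half-lives
#'
#' Effective half-life of measured activity decline:
#' `1/T_eff = 1/T_bio + 1/T_phys`. A biological half-life of `Inf` denotes no
#' biological clearance, so the effective half-life is the physical one.
#'
#' @param biological Biological half-life, hours (> 0, may be `Inf`).
#' @param physical Physical half-life, hours (> 0, may be `Inf`).
#' @return Effective half-life in hours; never exceeds either input.
#' @export
combine_half_lives <- function(biological, physical) {
  if (any(biological <= 0) || any(physical <= 0))
    stop("half-lives must be > 0")
  1 / (1 / biological + 1 / physical)
}

#' Biological half-life that yields a given effective half-life
#'
#' Inverse of [combine_half_lives()]: `1/T_bio = 1/T_eff - 1/T_phys`. Used by
#' the virtual-patient generator to target published effective half-lives.
#'
#' @param effective Effective half-life, hours; must not exceed `physical`.
#' @param physical Physical half-life, hours.
#' @return Biological half-life in hours (`Inf` when effective == physical).
#' @export
biological_half_life <- function(effective, physical) {
  if (any(effective <= 0) || any(physical <= 0))
    stop("half-lives must be > 0")
  if (any(effective > physical))
    stop("effective half-life cannot exceed the physical half-life")
  1 / (1 / effective - 1 / physical)
}

#' Mean absorbed energy per decay
#'
#' Electron energy is assumed fully absorbed locally (Lu-177 electron range is
#' far below organ dimensions); the photon component is weighted by a
#' geometry-dependent absorbed fraction.
#'
#' @param nuclide A `radionuclide` object.
#' @param photon_absorbed_fraction Fraction of emitted photon energy absorbed
#'   in the source region, in `[0, 1]`.
#' @return Absorbed energy per decay, MeV.
#' @export
energy_per_decay <- function(nuclide, photon_absorbed_fraction) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (any(photon_absorbed_fraction < 0) || any(photon_absorbed_fraction > 1))
    stop("photon_absorbed_fraction must lie in [0, 1]")
  nuclide$mean_electron_energy +
    photon_absorbed_fraction * nuclide$mean_photon_energy
}
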