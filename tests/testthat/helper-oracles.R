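# Independent brute-force oracles used across the suite.

# numerical TIAC: trapezoid on a dense grid out to 10 effective half-lives of
# the slowest component, plus the analytic tail of the remaining integral
tiac_numeric <- function(amplitudes, rates, n_grid = 20000) {
  t_end <- 10 * log(2) / min(rates)
  tt <- seq(0, t_end, length.out = n_grid)
  f <- function(t) colSums(amplitudes * exp(-outer(rates, t)))
  y <- f(tt)
  trap <- sum((y[-1] + y[-length(y)]) / 2 * diff(tt))
  tail <- sum(amplitudes * exp(-rates * t_end) / rates)
  trap + tail
}

# numerical absorbed dose: integrate instantaneous power / mass over time
# (activity fraction -> decays/s per GBq -> W) on a dense grid + tail
dose_numeric <- function(amplitudes, rates, mass_kg, e_mev, n_grid = 20000) {
  j_per_decay <- e_mev * 1.602176634e-13
  t_end <- 10 * log(2) / min(rates)
  tt <- seq(0, t_end, length.out = n_grid)          # hours
  act <- colSums(amplitudes * exp(-outer(rates, tt)))  # FIA
  power <- act * 1e9 * j_per_decay / mass_kg           # Gy/s per GBq
  trap <- sum((power[-1] + power[-length(power)]) / 2 * diff(tt)) * 3600
  tail <- sum(amplitudes * exp(-rates * t_end) / rates) * 1e9 * 3600 *
    j_per_decay / mass_kg
  trap + tail
}

# noiseless monoexponential TAC with a given effective decay rate
make_mono_tac <- function(region = "whole_body", a = 1, t_eff = 35,
                          times = c(0.5, 3, 24, 48, 72, 168)) {
  tac(region, times, a * exp(-log(2) / t_eff * times))
}

# a small noiseless virtual patient with whole body + kidneys (+ optional
# bone lesion and blood), used for round-trip tests
make_test_patient <- function(te_wb = 35, te_k = 81, a_k = 0.05,
                              with_lesion = FALSE, with_blood = FALSE,
                              administered = 5.8) {
  t_phys <- 159.53
  kin <- list(
    region_kinetics("whole_body", 1.0, biological_half_life(te_wb, t_phys)),
    region_kinetics("kidneys", a_k, biological_half_life(te_k, t_phys)))
  masses <- c(whole_body = 73, kidneys = 0.31)
  if (with_lesion) {
    kin <- c(kin, list(region_kinetics(
      "bone_metastasis_1", 0.01, biological_half_life(44, t_phys))))
    masses["bone_metastasis_1"] <- 0.010
  }
  if (with_blood)
    kin <- c(kin, list(region_kinetics("blood", c(0.9, 0.1), c(1, 15))))
  virtual_patient(administered, kin, masses)
}
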