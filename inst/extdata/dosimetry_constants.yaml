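# Physical and phantom constants used by ludosim.
# version: 1
#
# Lu-177 decay data: ICRP Publication 107 radionuclide decay data.
#   mean_electron_energy = beta + conversion-electron + Auger energy per decay
#   mean_photon_energy   = gamma + x-ray energy per decay
# Phantom masses: ICRP Publication 89 reference adult.
# sphere_phi: photon self-absorbed fraction for unit-density spheres,
#   phi(m) = c1 * m^c3 / (c2 + m^c3)  (m in grams),
#   least-squares fit to representative published absorbed fractions for
#   ~208 keV photons in unit-density spheres (anchors listed below);
#   phi(73 kg) = 0.350, the value used for whole-body photon self-dose.
version: 1
nuclides:
  lu177:
    name: Lu-177
    physical_half_life_h: 159.53
    mean_electron_energy_mev: 0.1479
    mean_photon_energy_mev: 0.0335
phantom:
  whole_body_kg: 73.0
  kidneys_kg: 0.310
  liver_kg: 1.8
  red_marrow_kg: 1.17
  blood_volume_l: 5.0
sphere_phi:
  c1: 0.4429687
  c2: 23.6419405
  c3: 0.4014561
  fit_anchors:
    mass_g: [1, 10, 100, 1000, 10000, 73000]
    phi:    [0.020, 0.045, 0.090, 0.180, 0.280, 0.350]
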