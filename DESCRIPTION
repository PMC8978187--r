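Package: ludosim
Title: Internal Dosimetry Pipeline for Lu-177 Peptide-Targeted Radionuclide Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: MIRD-schema internal dosimetry for Lu-177 radiopharmaceutical
    therapy, built around the hybrid planar/SPECT workflow used in
    first-in-humans Lu-177-FAP-2286 treatment: conjugate-view quantification
    of serial anterior/posterior whole-body scans normalized to injected
    activity, rescaling of regional time-activity curves with a single
    quantitative SPECT measurement, mono- and biexponential time-activity
    curve fitting with corrected-AIC model selection, time-integrated
    activity coefficients, and OLINDA-equivalent absorbed doses (Gy/GBq)
    for whole body, mass-adapted ICRP-89 organs, unit-density tumor
    spheres, and red marrow by both the blood-based and whole-body
    methods. Includes a seeded virtual-patient simulator (biexponential
    region kinetics, physical decay, conjugate-view attenuation, Poisson
    counting noise) that stands in for the non-public clinical raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
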