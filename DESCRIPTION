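Package: petdosim
Title: Internal Radiation Dosimetry and Pharmacokinetics for Serial Whole-Body PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of serial whole-body PET tracer studies:
    standardized uptake values (SUV), organ time-integrated activity
    coefficients (TIAC) from sparse time-activity curves with analytic
    extrapolation, urinary-excretion fitting and a voiding-bladder model,
    MIRD-schema absorbed dose and ICRP-103 effective dose computation,
    mono-exponential plasma pharmacokinetics, and cohort tumor-uptake
    statistics. Includes a synthetic-cohort generator with analytic ground
    truth so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
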