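Package: dormouseTb
Title: Active-Season Body-Temperature Analysis for Heterothermic Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing implanted-logger body-temperature (Tb) time
    series from hibernating rodents during the active season, developed around
    the edible dormouse (Glis glis). Classifies samples into torpor, euthermia
    and slight hyperthermia, assembles thermal bouts, computes daily and
    weekly activity metrics (hours per day above 40 degrees C), detects
    hibernation onset and the parturition step change in daily mean Tb, and
    fits random-intercept mixed models with AR(1) residual correlation and
    type-3 Wald tests. Includes a calibrated synthetic trace generator that
    emulates annual dormouse Tb/Ta records with ground-truth sidecars so the
    full pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    car,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
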