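Package: lakechl
Title: Satellite Lake Chlorophyll Match-Up Calibration and Patchiness Mapping
Version: 0.1.0
Authors@R:
    person("lakechl", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for turning satellite-derived inherent optical property
    (IOP) fields of lakes into quality-controlled chlorophyll-a products and
    recurring-patchiness maps. Implements quality-flag masking with an
    IdePix/C2RCC-style flag vocabulary, shoreline-buffer and shallow-water
    (Secchi-based) exclusion, satellite vs in-situ match-up selection with
    macropixel homogeneity screening, a regionalized chlorophyll-from-IOPs
    calibration with refitting and goodness-of-fit diagnostics, and per-pixel
    quantile-frequency composites that identify representative sampling
    areas. Ships a synthetic scene generator with known ground truth so the
    full pipeline is testable end to end without any satellite download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
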