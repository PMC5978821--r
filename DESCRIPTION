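Package: thermolimp
Title: Paired-Limb Infrared Thermography Analysis for Acute Paediatric Limp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing radiometric thermal video of the lower limbs
    in children presenting with an acute undifferentiated limp. Provides
    temperature-raster and recording-manifest input/output, deterministic
    selection of the best frames from a thermal video, paired rectangular
    region-of-interest (ROI) measurement with contralateral mirroring, the
    percentage skin-temperature asymmetry statistic, and cohort-level
    descriptive and group summaries (median, interquartile range, percentage
    difference of group medians). A synthetic thermal-phantom generator
    emulates paired lower-limb silhouettes with a proximodistal temperature
    gradient, an optional focal hotspot, sensor noise at the camera's noise
    equivalent temperature difference scale, and motion-corrupted frames, so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
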