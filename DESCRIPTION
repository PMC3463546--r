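Package: pseudophakia
Title: Personalized Ray-Traced Pseudophakic Eye Models for Intraocular
    Lens Power Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds individual pseudophakic (post-cataract) eye models from
    corneal elevation topography and ocular biometry, traces them with an
    exact polychromatic 3-D ray-tracing engine, scores retinal image
    quality with a contrast-sensitivity-weighted modulation transfer
    function merit, and selects the intraocular lens power that optimizes
    it.  Corneal surfaces are interpolating bicubic splines over a 59x59
    elevation grid, so the method works identically for normal and
    post-LASIK corneas where keratometry-based formulas fail.  Includes a
    synthetic topography and cohort generator, an SRK/T comparator, and
    statistical tooling for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
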