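Package: traitscape
Title: Trait Dispersion Along Soil Resource Gradients at Multiple Spatial
    Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quadrat-based analysis of plant functional trait dispersion in
    large forest census plots. Computes abundance-weighted functional
    dispersion (FDis) in corrected principal-coordinate trait space,
    standardized effect sizes against taxa-shuffle null models, ordinary
    kriging of point soil samples onto quadrat grids, principal-component
    soil gradients with parallel-analysis axis retention, and
    torus-translation tests of dispersion-environment correlations across
    spatial scales. Includes a synthetic forest-plot generator in which
    local trait filtering responds to designated limited, non-limited and
    saturated soil resources, so the full pipeline can be validated
    end-to-end without access-controlled census data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
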