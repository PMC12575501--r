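Package: renalrod
Title: Respiratory Motion of Stented Renal Arteries via Discrete Elastic Rods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale digital-twin analysis of respiration-induced renal
    artery deformation before and after fenestrated endovascular aneurysm
    repair (fEVAR). Generates reproducible synthetic abdominal aortas with
    renal branches, deploys bridging stent-grafts from a catalog of
    commercially available sizes, brings a discrete elastic rod surrogate of
    the artery (with a stiffer stented segment) to static equilibrium under
    respiratory displacement boundary conditions, and quantifies the result
    with centerline morphometrics (Menger curvature, branching angle,
    end-stent angle), iterative-closest-point registration, corresponding
    point centerline distances, a stent-graft placement accuracy score, and
    a protrusion-length criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
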