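Package: canalaccess
Title: Anatomical Feasibility Analysis of Keyhole Drill Access to the
    Semicircular Canals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and evaluates minimally invasive (keyhole) drill
    trajectories from the mastoid surface to the three semicircular canals
    of the inner ear, as required for vestibular implantation. Provides a
    seeded generator of synthetic temporal-bone anatomy, procedural surface
    processing (region-of-interest cropping, outer-surface extraction,
    lateral skull base and sigmoid-sinus bounding surfaces, drill
    entry-point regions), canal centreline extraction with electrode-target
    and fenestration-site placement, signed-distance-field clearance
    computation for a stepped drill profile, canal entry angles and an
    idealized exposed-lumen-area model, accessibility classification over
    entry regions, fenestration-site sweeps, mutual optimization of three
    trajectories under a shared-mastoidectomy constraint, and per-case and
    cohort reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
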