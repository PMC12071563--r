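Package: mitohotspot
Title: Mitotic Hotspot Computation and Reader-Agreement Analysis for
    Breast Carcinoma Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes mitotic hotspots on whole-slide images of invasive
    breast carcinoma from per-slide mitosis detections and tumor-region
    polygons: confidence filtering, patch-grid candidate generation,
    core/context radius counting, hotspot scoring and greedy selection of
    non-overlapping 2 mm^2 counting zones; derives mitotic counts and
    Elston-Ellis mitotic scores (grades 1-3); and provides the
    reader-agreement statistics used in clinical evaluations of such
    tools: accuracy against an expert consensus, linear weighted Cohen's
    kappa with asymptotic or bootstrap confidence intervals, intraclass
    correlation ICC(2,1), and counting-zone intersection rates, with
    subgroup reports. Includes generators for synthetic slides (Poisson
    background plus planted mitosis clusters inside tumor polygons) and
    simulated reader scores so the whole pipeline is testable without any
    slide raster data, plus CSV/GeoJSON/JSON input and output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mgcv,
    optparse,
    stats,
    utils
Suggests:
    e1071,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
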