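Package: diarrscan
Title: Space-Time Cluster Detection for District-Level Disease Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retrospective cluster analysis of monthly disease counts reported
    by administrative units, built around a discrete-Poisson Kulldorff scan
    statistic with circular spatial windows, temporal intervals and space-time
    cylinders, and Monte Carlo hypothesis testing. Includes compound-growth
    population projection to person-time denominators, incidence rates,
    ratio-to-moving-average seasonal decomposition with a deseasonalized
    linear trend, excess-risk (observed/expected) tables, GeoJSON cluster
    export, and a synthetic panel generator with planted clusters of known
    relative risk for method validation. Reference values from a published
    district-level analysis of under-five diarrhea in Sidama Zone, Southern
    Ethiopia (July 2011 to June 2017) are shipped as fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    geosphere,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
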