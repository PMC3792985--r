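Package: bloomrisk
Title: Apple Bloom Phenology and Blossom Frost Risk Projection Under
    Climate Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for projecting apple (Malus domestica) bloom dates and
    blossom frost risk from ensembles of regional climate model temperature
    series.  Implements seven chilling/forcing phenological models (thermal
    time, sequential and parallel chilling-forcing, modified Utah, and
    day-length-extended variants), bound-constrained simulated-annealing
    calibration with leave-one-out cross-validation, quantile-mapping bias
    correction, temporal spline interpolation and spatial aggregation of
    temperature fields including ordinary kriging, 30-year blossom frost
    risk statistics, Hawkins-Sutton-style partitioning of projection
    variance into internal, climate-run and impact-model components with
    time-of-emergence estimation, and Mann-Kendall and Cox-Lewis trend
    tests.  A seeded synthetic climate and phenology generator provides
    reproducible ensembles for testing the full projection chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
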