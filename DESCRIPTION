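Package: conserve30
Title: Scenario Construction and Social Profiling for 30x30 Protected-Area Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing who lives in and near areas selected under
    alternative 30x30 (KMGBF Target 3) protected-area expansion scenarios on an
    equal-area grid. Provides a gridded raster engine (coverage rasterization,
    aggregation, buffering, zonal statistics), protected-area record filtering
    and baseline construction, three scenario builders (minimum-shortfall
    biodiversity prioritization, NCP priority ranking, Indigenous and
    traditional territories with replicated random trimming), a social profiler
    (population, Human Development Index structure, livelihoods, continental
    disaggregation, scenario overlap), a seeded synthetic-world generator so the
    whole pipeline runs without external downloads, and a reproducible pipeline
    driver with manifests and caching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
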