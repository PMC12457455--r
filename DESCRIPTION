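Package: foresttraj
Title: Trajectories of Forest Change from Annual Land-Cover Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes spatio-temporal trajectories of forest change from
    annual categorical land-cover grids. Provides per-cell dominant land-cover
    transition detection, the unlike-adjacency fragmentation metric under
    Queen contiguity with combinatorial minimum/maximum bounds, the Landscape
    Configuration Index (LCI), interval-based relative rates and amounts of
    forest change, persistence classification with exclusion filters,
    non-parametric group comparisons (Cliff's delta), penalized smooth-effect
    summaries, and a seeded synthetic landscape generator so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    geosphere,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
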