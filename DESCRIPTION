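Package: soilcap
Title: Soil Heavy-Metal Environmental Capacity and Health-Risk Warning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Material-balance environmental-capacity analysis for heavy
    metals in agricultural topsoil. Computes per-element static, residual
    and dynamic (multi-year horizon) capacities from background, risk
    reference and measured status concentrations; aggregates them by
    administrative unit; scores each unit with an improved Nemerow
    comprehensive index over range-normalized residual capacities and a
    five-grade capacity/health-risk classification; and interpolates
    sample-level capacities onto regular grids by inverse distance
    weighting with Esri ASCII raster export. Ships regulatory standards
    and city-level capacity tables for the nine-city Pearl River Basin
    urban agglomeration as plain-text fixtures, plus a seeded synthetic
    sampling-campaign generator with known ground truth, so the full
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
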