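Package: aqhia
Title: Air Quality and Health Co-Benefits of Urban Climate Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, end-to-end pipeline for estimating the air quality and
    health co-benefits of city-level climate mitigation and adaptation
    policies. Generates synthetic gridded monthly PM2.5 surfaces with a
    scenario-scaled point-source plume and a spatially heterogeneous
    population raster, aggregates representative months into seasonally
    weighted annual exposure surfaces, computes unweighted and
    population-weighted city means, and converts exposure differences between
    scenarios into excess all-cause mortality under log-linear and GEMM
    (Global Exposure Mortality Model) exposure-response functions with
    confidence-interval propagation. Includes air-quality attainment rollback
    counterfactuals (NCAP, NAAQS, WHO AQG), scenario energy and CO2
    bookkeeping (cool roofs, renewable substitution), and model-vs-monitor
    seasonal bias diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
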