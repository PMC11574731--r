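Package: paindex
Title: Procedure Access Inequality Index for Hospital Discharge Data
Version: 0.1.0
Authors@R: person("paindex", "maintainers", email = "maintainers@paindex.org",
    role = c("aut", "cre"))
Description: Computes the Procedure Access Inequality (PAI) index, a
    standardized, prevalence-adjusted measure of geographic inequality in
    inpatient-procedure utilization across residential zip codes, together
    with procedure-level hospital-market Herfindahl-Hirschman concentration
    (HHI). Includes indirect age-sex standardization of baseline utilization,
    ranked tables, cross-sectional and longitudinal regressions of inequality
    on hospital counts, tercile summaries of procedure characteristics, a
    synthetic encounter-data simulator with a planted access-inequality
    mechanism for end-to-end testing without restricted discharge data, and a
    command-line interface wiring the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
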