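Package: woodbkm
Title: Bookkeeping Model-Data Integration for Woody Biomass Carbon Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A gridded bookkeeping carbon model that assimilates an annual
    woody-biomass carbon-density time series, tracks legacy land-use fluxes
    through exponentially relaxing excess pools, and decomposes net changes in
    woody-vegetation carbon into an anthropogenic land-use flux (E_LUC,B) and
    an environmental sink (S_LAND,B) via paired transient and fixed
    simulations. Includes density screening (uniform and percentile thresholds
    with barycentric gap interpolation), a diagnostic suite (interannual
    variability, assimilation bias, temporal agreement, land-use intensity,
    detrended Spearman climate correlations, regional aggregation), a
    synthetic-world generator with an exact ground-truth ledger, conservative
    regridding, and CSV/JSON input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
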