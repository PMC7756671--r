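Package: peatflux
Title: Static-Chamber Greenhouse-Gas Flux Estimation and Upscaling for
    Peatland Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for processing static closed-chamber N2O and CH4
    measurements from peatland monitoring campaigns: per-chamber flux
    estimation by linear regression of headspace concentration against time
    with leave-one-out quality control, ideal-gas unit conversion to areal
    fluxes, Monte-Carlo minimum detectable flux in the style of Parkin et
    al. (2012), soil covariates (water-filled pore space, net N
    mineralization and nitrification rates), aggregation of replicate
    chambers to monthly stratum means and trapezoid-integrated annual
    budgets with Gaussian error propagation and area-weighted site-scale
    upscaling, interquartile-range hotspot detection, environmental driver
    regressions (log-offset linear, exponential, polynomial, class-binned),
    and a synthetic campaign generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
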