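Package: pelagicsync
Title: Forage-Fish Community Synchrony and Marine Heatwave Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative tools for analysing pelagic food-web responses to
    marine heatwaves: detection of heatwave events from daily sea surface
    temperature series using a day-of-year percentile climatology,
    diet-based forage-fish availability indices and rolling variance-ratio
    portfolio effects, multifrequency acoustic dB-difference classification
    of macrozooplankton with echo-integration (NASC) indices, lognormal
    mixture decomposition of length-frequency distributions, fish
    energetics (carbon:nitrogen energy-density model, mixed-effects annual
    energy estimates), and standardized anomaly indices for predator
    surveys. Includes seeded synthetic-data generators that emulate the
    statistical structure of each input stream, so the full pipeline can be
    exercised and validated without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    lme4,
    emmeans,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
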