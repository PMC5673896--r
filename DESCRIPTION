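Package: poreflux
Title: Pore-Scale Organic Matter Chemistry and Core-Scale Greenhouse-Gas
    Fluxes for Soil Rewetting Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing laboratory soil-core rewetting experiments
    that pair ultrahigh-resolution mass spectrometry of pore water with
    closed-chamber greenhouse-gas measurements. Implements FT-ICR-MS peak-list
    processing (signal-to-noise filtering, internal calibration on CH2
    homologous series, exhaustive CHONSP molecular-formula assignment,
    Van Krevelen compound classification, relative abundance and molecular
    richness), chamber CO2/CH4 flux computation from headspace concentration
    series with trapezoidal cumulative emissions, capillary suction to
    pore-throat-diameter mapping, and the factorial inference layer
    (principal components of compound-class profiles, REML linear mixed
    models with core as a random effect, least-significant-difference letter
    displays, treatment-ratio contrasts). A synthetic-data generator with
    known ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
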