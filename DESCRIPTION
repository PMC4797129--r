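Package: forenSTR
Title: Expert-System STR Electropherogram Analysis and Developmental Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for fully automated short tandem repeat (STR) genotyping from
    multi-channel capillary-electrophoresis fluorescence traces. Provides signal
    conditioning (baseline removal, spectral colour correction), peak detection,
    internal-lane-standard size calibration, allelic-ladder bin calibration,
    rule-based allele calling (analytical threshold, stutter filtering,
    heterozygote peak-height-ratio checks), and CODIS-ready outputs (allele
    tables, CMF-style XML, ABIF .fsa traces, electropherogram plots). A synthetic
    electropherogram simulator with controllable stutter, heterozygote imbalance,
    dye crosstalk, degradation and template-mass-dependent allele dropout supports
    desk-scale developmental validation: sizing precision, resolution, peak height
    ratio, concordance, reproducibility tabulation and sensitivity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'panel.R'
    'utils.R'
    'sizing.R'
    'calling.R'
    'io-outputs.R'
    'io-abif.R'
    'metrics.R'
    'simulate.R'
    'cli.R'
    'signal.R'
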