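Package: dfpneumo
Title: Simulation and Quantitative Analysis of X-Ray Dark-Field
    Radiography of Pneumothorax
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-simulates grating-interferometer (fringe-scanning)
    chest radiography of a stylized porcine thorax phantom, before and
    after induction of lateral or dorsal pneumothoraces, and implements
    the quantitative analysis chain used in large-animal dark-field
    imaging studies: sinusoid stepping-curve retrieval of transmission
    and dark-field images, Gaussian and binomial post-processing filters
    with their white-noise dose-equivalence factor, ROI-based
    contrast-to-noise ratios between inflated lung and pleural gas,
    projected-area quantification of retro-diaphragmatic lung, and
    paired statistics with noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
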