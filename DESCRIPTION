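Package: benthoscape
Title: Predicting Epi-Macrobenthic Diversity from Full-Waveform Bathymetric
    LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for predicting epi-macrobenthic species
    diversity in shallow coastal waters from full-waveform bathymetric LiDAR.
    Includes a seeded synthetic benthoscape survey generator (depth model,
    seabed structural complexity, substratum truth, green-channel return
    waveforms, station quadrats), segmentation of waveforms into surface,
    water-column, transition and benthic returns with 16 shape statistics,
    quadrat diversity and abundance indices (species density, overall
    abundance, Simpson, Shannon, modified Pielou evenness), quadratic-surface
    terrain morphometry with six-type terrain classification, supervised
    substratum mapping with kernel Bray-Curtis dissimilarity and Pielou
    evenness rasters, a multi-learner benchmark (naive Bayes, regression and
    classification trees, gain-ratio tree, random forest, support vector
    machine, covering-rule inducer) scored by classification accuracy, AUC,
    information score and Brier score across 2-10 class discretizations,
    inverse-class-count trend fits, Moran's I spatial autocorrelation, and
    predictive diversity mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
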