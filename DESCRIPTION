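Package: bpcluster
Title: Clustering-Based Cuff-Less Blood Pressure Estimation from ECG/PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Continuous cuff-less blood pressure estimation from paired
    ECG and PPG waveforms. Extracts per-cardiac-cycle pulse transit time
    (PTT), PPG intensity ratio (PIR) and heart rate (HR) from ECG/PPG,
    and systolic/diastolic pressure from a reference arterial blood
    pressure channel; partitions the feature space with
    silhouette-selected k-means; fits one regression model (gradient
    boosting, random forest or multilayer perceptron) per cluster; routes
    new samples by nearest centroid; and aggregates per-cluster errors by
    weighted arithmetic mean. Includes a beat-synchronized synthetic
    waveform simulator with known ground truth, and BHS/AAMI-standard
    grading plus Bland-Altman analysis of the resulting estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    ranger,
    xgboost,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
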