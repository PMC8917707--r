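Package: netmotion
Title: Accelerometer-Based Classification of Bed Net Use Behaviours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring long-lasting insecticidal net (LLIN) use with
    net-mounted triaxial accelerometers. Simulates annotated accelerometer
    recordings for five net-use behaviours (unfurling a net, entering, sleeping
    or no activity, exiting, folding a net up), reduces tagged 20-second windows
    to per-epoch summary features (per-axis means and standard deviations and a
    displacement-magnitude sum), trains random-forest classifiers under three
    nested label schemes, and evaluates them with confusion matrices, per-class
    sensitivity and specificity, one-vs-rest ROC curves, and DeLong variance
    estimates for AUC confidence intervals and curve comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
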