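Package: carieslens
Title: Detection and Classification of Occlusal Caries from Tooth Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of color photographs of extracted-tooth occlusal
    surfaces. A mask-algebra detection pipeline (contrast enhancement, grayscale
    conversion, Otsu binarization, contour finding, and saturated mask
    subtraction) isolates carious-lesion regions; five shape and texture
    features (length, width, smoothness, area ratio, convex area) quantify each
    lesion; and five standard classifiers compared under stratified 10-fold
    cross-validation separate early (visually non-cavitated) from late
    (cavitated) lesions. Includes an overlap-based evaluation protocol against
    expert annotations and a deterministic tooth-phantom generator with ground
    truth masks for end-to-end benchmarking without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    png,
    pracma,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
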