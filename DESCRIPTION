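Package: myomorph
Title: Morphometric Classification of Myoepithelial Cell Nuclei in Breast Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometric analysis of myoepithelial cell nuclei for
    grading breast intraductal proliferative lesions (Normal, usual ductal
    hyperplasia, low- and high-grade ductal carcinoma in situ). Implements a
    full image-analysis pipeline: synthetic duct-image generation with ground
    truth, optical-density stain modelling, nucleus segmentation in both
    hematoxylin-eosin (difference-of-Gaussian/Hough detection plus a polar
    dynamic-programming snake) and p63 immunohistochemistry (random-forest
    pixel classification) images, a 32-feature shape/intensity/texture vector
    per nucleus with a central-80% size trim, RBF-kernel support-vector
    classification with F-score feature ranking, weighted-majority aggregation
    of cell predictions to duct and patient level, and confusion-matrix
    evaluation (accuracy, Cohen's kappa, benign-vs-DCIS collapse).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    randomForest,
    e1071,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
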