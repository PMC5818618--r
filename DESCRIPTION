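Package: sqccradiomics
Title: Radiogenomic Analysis of Lung Squamous Cell Carcinoma CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for radiogenomic analysis of lung squamous
    cell carcinoma (SQCC). Extracts 52 quantitative CT features from tumor
    volumes with co-registered masks (global, histogram-based, lung
    cancer-specific, shape, gray-level co-occurrence and size-zone texture),
    quantifies emphysema on inspiratory CT using the -950 HU threshold, maps
    somatic mutation tables to five SQCC signaling-pathway alteration labels
    (redox stress, apoptosis, proliferation, differentiation, chromatin
    remodelers), and runs category-wise feature selection with univariate and
    multivariate logistic and Cox proportional-hazards models, reporting odds
    ratios, hazard ratios and AUCs. Includes synthetic phantom and cohort
    generators with known ground truth so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    survival,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
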