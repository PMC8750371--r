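Package: petResponse
Title: Quantitative Imaging Biomarkers and Treatment-Response Assessment for
    Longitudinal Whole-Body FDG PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-segmentation quantification of metastatic disease burden on
    longitudinal 18F-FDG PET/CT. Converts PET activity to SUV (body weight)
    and SUL (Janmahasatian lean body mass), computes four imaging biomarkers
    from lesion segmentations (PERCIST-style SULpeak with a 1.2-cm spherical
    VOI, total lesion glycolysis via connected-component labeling, and the
    PET Bone/Liver Indices of skeletal and hepatic tumor burden), evaluates
    segmentations against ground truth (mean and global Dice, lesion-wise
    detection with a 50 percent overlap rule), and assesses treatment
    response from baseline/follow-up biomarker changes (ROC/AUC, Youden
    cutoff, paired DeLong test, Lin's concordance). Includes a synthetic
    whole-body phantom cohort generator with exact ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'labeling.R'
    'biomarkers.R'
    'io.R'
    'morphology.R'
    'petResponse-package.R'
    'suv.R'
    'phantom.R'
    'response.R'
    'segeval.R'
    'pipeline.R'
    'resample.R'
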