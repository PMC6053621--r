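Package: earcount
Title: Wheat Ear Segmentation and Counting from Field Images via
    Superpixel Patches, Multi-Feature Weighting and a Twin Support
    Vector Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments and counts wheat ears (spikes) in RGB field images.
    The pipeline generates SLIC superpixels, extracts fixed 20x20 patches
    at superpixel weighted centers, describes each patch with colour
    coherence vectors (CCV), grey-level co-occurrence matrix (GLCM)
    statistics and the MPEG-7 edge histogram descriptor (EHD), fuses the
    descriptors by per-class importance weighting and kernel PCA, and
    classifies patches with a twin support vector machine (TWSVM) whose
    two non-parallel hyperplanes are fitted by solving the dual quadratic
    programs. Patch labels are painted back onto superpixels, median
    filtered, and ears are counted as connected components. Includes a
    seeded synthetic field-scene generator with exact ground truth,
    noise-injection utilities, the standard segmentation quality
    indicators (Qseg, Sr, SSIM, precision, recall, F-measure) and a
    count-regression report, plus a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    withr,
    generics,
    rlang,
    tibble,
    dplyr,
    ggplot2,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
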