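Package: stromaquant
Title: Quantification of Bioengineered Airway Stroma Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image, mechanical, and transcriptomic quantification for 3D
    bioengineered airway-stroma tissue models. Implements second-harmonic
    generation (SHG) collagen-fraction measurement, gray-level co-occurrence
    matrix (GLCM) correlation texture analysis with exponential
    correlation-length fitting, fluorescence morphometry (nuclei counting,
    protein area per cell, micro-tissue diameter), spherical nano-indentation
    stress-strain analysis under the Hertz contact model, differential
    expression post-processing (counts-per-million gene filtering, fold-change
    and FDR thresholding, concordance partition of two contrasts), one-way
    ANOVA with Tukey HSD group comparison, and synthetic-data generators with
    known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
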