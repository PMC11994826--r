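Package: rsathresh
Title: Multilevel Image Thresholding with a Gbest-Augmented Reptile Search Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel thresholding of grayscale and RGB images by maximizing
    Otsu between-class variance or Kapur entropy over 256-bin intensity
    histograms. The search engine is a reptile search algorithm (RSA) whose
    four phase updates (high walking, belly walking, hunting coordination,
    hunting cooperation) are augmented with a particle-swarm global-best
    velocity operator and elitist greedy selection. Includes an exhaustive
    enumeration oracle for verification, segmentation quality metrics (RMSE,
    PSNR, SSIM), a Friedman-rank benchmark harness for comparing optimizers,
    synthetic image and histogram generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
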