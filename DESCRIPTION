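Package: ctsr
Title: Thin-Slice Chest CT Super-Resolution from Two Orthogonal Thick-Slice Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuses a 5 mm axial and a 5 mm coronal CT series into a single
    registered low-resolution volume on the thin-axial grid by world-coordinate
    trilinear resampling and voxelwise averaging, then synthesizes thin-slice
    images with plane-selective deep super-resolution networks (modified SRCNN,
    VDSR, SRResNet and EDSR with 1:1 upsampling). Includes minimal DICOM CT
    series input/output with series admission rules and deidentification, a
    seeded synthetic chest phantom generator for fully reproducible end-to-end
    experiments, ROI-aware PSNR/SSIM evaluation (whole image, body area, lung
    fields), and one-sided Wilcoxon signed-rank comparisons with Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
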