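Package: adchist
Title: ADC Histogram Analysis of Rectal Tumor Diffusion MRI with Precise and
    Non-Precise Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-b-value diffusion-weighted MRI phantoms of rectal
    tumors with surrounding contaminating tissues, fits voxelwise apparent
    diffusion coefficient (ADC) maps with a mono-exponential decay model, and
    extracts first-order histogram metrics from precise (tumor-tracing) and
    non-precise (circular/oval with margin) volumes of interest. Provides
    intraclass correlation ICC(A,1) and Bland-Altman agreement statistics, a
    percentile sweep identifying the non-precise histogram surrogate for the
    precise mean ADC, and Holm-Bonferroni-corrected group comparisons of
    histogram metrics against binary prognostic labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
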