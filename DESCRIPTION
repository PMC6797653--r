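Package: infoval
Title: Informational Value of Reverse-Correlation Classification Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Objective, parameter-free assessment of signal in reverse-correlation
    classification images. Quantifies the informational value (infoVal) of a
    classification image as a modified z-score relating the image's vector length
    to a Monte-Carlo reference distribution of vector lengths obtained under fully
    random responding on the identical stimulus set. Includes the sinusoid
    stimulus-noise model used in two-image forced-choice (2IFC) tasks, an
    ideal-observer simulation harness for Type-I error and power studies, and
    companion data-quality metrics: the objective discriminability ratio, pixel-wise
    test-retest correlation, multidimensional scaling of classification-image
    distances, and cumulative-trials infoVal curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
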