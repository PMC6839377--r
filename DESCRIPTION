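Package: doseagree
Title: Dose Comparison Techniques for Patient-Specific Radiotherapy QA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing planned and measured radiotherapy dose
    distributions for patient-specific pretreatment quality assurance.
    Implements global- and local-normalization gamma evaluation, the
    maximum allowed dose difference (MADD) technique in box and quadrature
    form, and divide-and-conquer regional gamma analysis with isodose-band
    specific dose criteria, together with a synthetic planned/measured
    cohort generator (delivery-error injection and detector down-sampling)
    and a correlation study of agreement-index behaviour across techniques,
    criteria and lower dose thresholds using ordinary least squares
    regression with Sidak-corrected significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
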