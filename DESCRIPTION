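Package: tearspec
Title: Chemometric Analysis of Tear-Fluid SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for surface-enhanced Raman (SERS) spectra of human
    tears aimed at discriminating healthy, mild-cognitive-impairment and
    Alzheimer's subjects. Provides wavelet (bior6.8) background and noise
    removal, standard-normal-variate scaling, Lorentzian band deconvolution
    with band-intensity ratios, per-wavenumber class difference maps with
    one-way ANOVA significance, interval principal component analysis
    (i-PCA) over 22 fixed spectral windows, and Gaussian naive-Bayes
    classification of disease class from pooled interval scores. Includes a
    seedable synthetic tear-spectrum generator with class-dependent band
    tables so every stage can be exercised and validated without clinical
    data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
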