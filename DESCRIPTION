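Package: fsclex
Title: Form-to-Semantics Consistency and Age-of-Acquisition Modelling for Lexicons
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Word-level measures of form-meaning systematicity
    (phonology/orthography-to-semantics consistency) computed from a
    phonological or orthographic lexicon and a distributional semantic
    space, together with the statistical pipeline used to test their
    unique effect on age of acquisition: Box-Cox transformation and
    z-standardisation, nested ordinary-least-squares models compared by
    AIC differences, random-forest regression with permutation
    importance, principal-component disentanglement of collinear
    neighbourhood measures, permutation and lexicon-subsampling
    baselines, and a seeded synthetic-lexicon generator so the whole
    pipeline runs without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
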