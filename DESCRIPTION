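Package: masterytopics
Title: Diagnostic Classification and Structural Topic Modeling for
    Mixed-Format Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of scored items and constructed-response text
    from mixed-format tests.  A log-linear cognitive diagnosis model (LCDM)
    is fit to binary item scores by marginal maximum likelihood EM to
    classify examinees into skill-mastery profiles; the mastery statuses
    then enter a structural topic model (STM) as topical-prevalence
    covariates so that latent topic use in examinees' written answers can
    be predicted from their diagnosed skills.  Includes text preprocessing
    (stopword removal, Porter stemming, frequency and length filters),
    topic-number selection by semantic coherence, exclusivity and pairwise
    cosine similarity, covariate-effect estimation by the method of
    composition, and a synthetic-data generator so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    MASS,
    pracma
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
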