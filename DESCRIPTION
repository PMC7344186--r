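Package: ehrvec
Title: Medical Concept Embeddings from Longitudinal Visit Records via
    Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns dense vector representations of clinical concepts
    (symptoms, medications, lab tests, diagnoses) from time-ordered patient
    visit records. Each visit is treated as an unordered set of entities; a
    multi-head scaled dot-product self-attention encoder contextualizes the
    entity vectors within a visit, and a visit co-occurrence log-likelihood
    couples vectors across neighbouring visits of the same patient. Ships a
    seeded synthetic EHR generator with planted comorbidity topics, a plain
    skip-gram baseline, cosine-similarity ranking and per-dimension
    interpretability profiles, and an automated word-intrusion evaluation
    protocol, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
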