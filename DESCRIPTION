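Package: scmaudit
Title: Stereotype Content Audit of Age-Conditioned Language-Model Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An auditing pipeline for age-related stereotypes in text generated
    by large language models, organised around the Stereotype Content Model
    (warmth and competence, with sociability, morality, ability and
    assertiveness subdimensions). Provides corpus construction and sentence
    filtering, a deterministic synthetic embedding backend with a pluggable
    adapter for real sentence encoders, principal-component reduction and
    age-by-age cosine similarity, template-trained partial-least-squares
    scoring of warmth and competence, Welch's heteroscedastic one-way ANOVA
    across age groups, lexicon-based subdimension word counting with Zipf
    common-term filtering, and a seeded synthetic corpus generator with
    planted stereotype structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mixOmics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
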