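Package: hsq5d
Title: Five-Dimension Service-Quality Assessment from Online Patient Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Text-mining workflow for assessing health-care service quality
    from online patient reviews. Segments reviews into punctuation-delimited
    clauses, discovers topics with collapsed-Gibbs latent Dirichlet allocation
    and perplexity-based model selection, classifies clauses into five quality
    dimensions (expertise, service delivery process, communication attitude,
    empathy, outcome) with a shallow averaged n-gram embedding classifier,
    scores clause sentiment with a rule-based lexicon algorithm handling
    degree adverbs and negation, aggregates doctor-week dimension scores, and
    validates the dimensions with a two-way fixed-effects panel regression of
    patient demand with doctor-clustered standard errors. A synthetic-corpus
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
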