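Package: layglove
Title: Enriching Consumer Health Vocabularies with GloVe Embeddings and
    Lexical Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatically enriching consumer health vocabularies
    (lay synonyms of professional medical concepts) from a corpus of lay
    health text. Implements a full pipeline: Snowball-stemmed corpus
    preprocessing, construction of concept and seed-term ground truth from
    CUI-to-term mappings, corpus expansion with relational synsets
    (synonyms, hyponyms, hypernyms) from a pluggable lexical resource
    ranked by Resnik information-content similarity, GloVe-style
    log-bilinear word embeddings trained on a global co-occurrence matrix,
    cosine-similarity candidate ranking, and micro and macro
    precision/recall/F, NumCon and mean-reciprocal-rank evaluation against
    held-out synonyms. Includes a seeded synthetic benchmark generator
    with planted synonym groups and a deterministic toy lexical resource
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
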