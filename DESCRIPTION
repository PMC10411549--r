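Package: semcoh
Title: Semantic Coherence Metrics for Clinical Speech Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies semantic coherence in structured interview speech
    transcripts using word-embedding sentence vectors. Provides transcript
    ingestion with sentence-boundary annotation, a preprocessing chain
    (verbal-filler removal, stopword removal, lemmatization), loaders for
    word2vec-text and GloVe-text vector files, local (adjacent-sentence) and
    global (sentence-to-centroid) cosine-similarity coherence scores, and a
    correlational validation layer (Pearson, partial correlations,
    independent t-tests) against clinical outcome tables. A synthetic-data
    module generates topic-structured toy embedding spaces, topic-drift
    transcripts with ground-truth incoherence, and simulated clinical
    cohorts with stated score-outcome effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
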