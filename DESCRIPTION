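Package: pragmalang
Title: Computational Analysis of Pragmatic Language in Dialog-Act-Tagged
    Language Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying pragmatic language use in dialog-act-tagged
    language-sample transcripts from narrative and semi-structured
    conversational tasks. Implements a documented plain-text transcript
    dialect with maze and filled-pause markup, dictionary-based word-category
    classification with wildcard stems and composite categories, a-priori
    speech-act sequence statistics, Markov-chain estimation with
    Kullback-Leibler divergence-rate comparison and a permutation null,
    latent profile analysis (diagonal-covariance Gaussian mixtures fit by EM)
    with AIC/BIC/entropy and the bootstrap likelihood ratio test, and the
    surrounding group-comparison statistics (factorial ANCOVA with estimated
    marginal means, Wilks MANCOVA, chi-square/Fisher dispatch,
    Benjamini-Hochberg adjustment, partial correlations, intraclass
    correlation). A synthetic-transcript generator with planted group
    structure makes every analysis testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    car,
    emmeans,
    jsonlite
Config/testthat/edition: 3
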