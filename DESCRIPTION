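Package: gcn16
Title: Predicting 16S rRNA Gene Copy Number from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the 16S rRNA gene copy number (GCN) of bacteria and
    archaea directly from 16S gene sequences with a k-mer based stacked
    ensemble regressor (a multi-layer perceptron and a support vector
    regression on principal-component scores, aggregated by a ridge
    meta-learner), alongside the classical taxonomy-aggregation and
    phylogenetic hidden-state-prediction baselines (empirical probabilities,
    subtree averaging, Sankoff maximum parsimony, weighted-squared-change
    parsimony, independent contrasts). Includes GCN-aware correction of
    amplicon community profiles with mock-community evaluation by
    Bray-Curtis dissimilarity, Kernel SHAP attribution of k-mer features
    mapped onto alignment coordinates with per-locus mutation rates, and
    seeded simulators (trees, evolved sequences with true alignments,
    copy-number traits, lineages, mock communities) providing ground truth
    for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
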