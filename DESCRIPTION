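Package: ubisite
Title: Lysine Ubiquitylation Site Prediction with Feature-Subset Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of protein lysine ubiquitylation sites.
    Lysine-centered peptide windows are encoded with four feature families
    (grouped amino-acid composition, min-max normalized PSSM conservation
    scores, Atchley amino-acid factors, and intrinsic-disorder scores; 627
    features at the default window of 21). Informative feature subsets are
    extracted by greedy forward selection on normalized conditional mutual
    information, started from multiple ranks of the marginal
    mutual-information ordering, with a minimum-redundancy
    maximum-relevance baseline. One random-forest base classifier is
    trained per subset and predictions are aggregated by majority voting.
    Evaluation supports leave-one-protein-out jackknife, protein-grouped
    stratified k-fold cross-validation and independent tests with
    sensitivity, specificity, accuracy and the Matthews correlation
    coefficient, plus per-family and per-site provenance analysis of the
    selected subsets. A synthetic benchmark generator with a plantable
    flanking motif, surrogate PSSMs and disorder tracks provides
    ground-truth data for selector-recovery and null-control experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
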