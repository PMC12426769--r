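Package: condrec
Title: Quantitative Recommendation of Reaction Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage framework for recommending quantitative reaction
    conditions for organic synthesis. Given a reaction (reactants and
    products), the framework predicts the set of above-the-arrow agents
    (catalysts, reagents, solvents treated role-agnostically over a fixed
    vocabulary), a binned reaction temperature, and binned equivalence
    ratios for every reactant and agent. Agent sets are decoded
    autoregressively by beam search from a multi-label classifier trained
    with partition augmentation; temperature and amounts are binned
    classification heads trained with teacher forcing, the agent-amount
    head with a masked cross-entropy loss. The package includes
    chemistry-relevant popularity and nearest-neighbor baselines keyed on
    the most detailed reaction class, a full evaluation suite (relaxed and
    strict set accuracy, off-by-N accuracy, bin MAE, reaction-level
    categories, end-to-end exact match, pairwise win rates with Wilson
    intervals), and a synthetic-data generator with known
    substrate-to-condition rules so the whole pipeline can be exercised
    and verified without access to commercial reaction corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
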