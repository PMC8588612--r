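Package: molrl
Title: De Novo Molecule Design with Multi-Objective Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A SMILES-based recurrent language model for de novo molecular
    design, trained by policy-gradient reinforcement learning against
    multiple bioactivity objectives. Rewards are shaped either by a
    Pareto-front scheme (non-dominated sorting with Tanimoto-distance
    ranking within fronts) or by a dynamic weighted-sum scheme. Includes
    the surrounding machinery: SMILES tokenization and vocabulary
    construction, molecule featurization (ECFP6 fingerprints plus
    physico-chemical descriptors), QSAR model training on bioactivity
    tables, an agent/crossover/mutation exploration strategy, and an
    evaluation suite covering validity, desirability, uniqueness,
    Solow-Polasky diversity, substructure profiles and drug-likeness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    ranger,
    e1071,
    mixOmics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
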