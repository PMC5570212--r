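Package: nabind
Title: Predicting Mutation Effects on Protein-Nucleic Acid Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of the change in protein-nucleic acid
    binding free energy (ddG, kcal/mol) caused by single missense mutations.
    The mutated residue's environment in a PDB complex is summarised as a
    graph-based signature: cumulative counts of pharmacophore-typed atom
    pairs at increasing distance cutoffs, augmented with relative solvent
    accessibility, the distance from the mutation site to the nucleic acid
    and a pluggable protein-stability term. A Gaussian-process regressor
    maps signatures to ddG. Includes dataset handling with reverse-mutation
    augmentation, leakage-safe cross-validation, evaluation with outlier
    trimming and distance stratification, and synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    kernlab,
    methods,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
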