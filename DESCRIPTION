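Package: qsevo
Title: Quaternary Structure Variability and Evolution Across Protein
    Orthogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the variability of protein quaternary
    structure (QS) across orthogroups of homologous proteins, contrasting
    families that contain multifunctional ("moonlighting") proteins with
    families that do not. Classifies interface, surface and buried residues
    from solvent-accessibility tables; partitions homomer structures into QS
    topology classes from structural-alignment interface overlap; computes
    orthogroup-level QS diversity metrics including the Shannon index;
    reconstructs ancestral QS states on phylogenies by equal-rates Markov
    maximum likelihood and by ACCTRAN parsimony, with minimal-ancestor-
    deviation rooting and QS change-rate statistics; removes hierarchically
    redundant ontology terms before annotation-richness comparisons; and runs
    the group statistics (Wilcoxon rank-sum, tests of proportions, ANCOVA,
    Spearman partial correlation) with a study-wide Benjamini-Hochberg pass.
    A synthetic-data generator produces every input with known ground truth
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
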