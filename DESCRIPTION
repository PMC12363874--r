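Package: ceofis
Title: Evolution-Based Functional Impact Scores for Protein Variants via
    Subfamily Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the functional impact of amino-acid substitution
    variants from the conservation patterns of a protein-family multiple
    sequence alignment. Aligned homologs are clustered into subfamilies by
    combinatorial entropy optimization (CEO), a joint selection of a
    sequence partition and a set of specificity columns that are variable
    across the family but conserved within subfamilies. Each substitution
    receives a conservation score (family-wide residue-count log ratio), a
    specificity score (the same ratio within the query's subfamily), their
    mean as the functional impact score (FIS), a conjugate specificity
    score for the reverse substitution in subfamilies where the variant
    residue is conserved, an impact category, and a switch-of-function
    flag. Includes a seeded generator of synthetic alignments with planted
    subfamily structure for end-to-end validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
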