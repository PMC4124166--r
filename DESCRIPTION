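Package: lineageMK
Title: McDonald-Kreitman Tests and Lineage-Specific Acceleration Screens
    for Human Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Branch-specific substitution counting on four-species
    (human, chimpanzee, macaque, mouse) codon alignments by nucleotide-level
    parsimony with Nei-Gojobori (1986) site and pathway counting,
    derived-allele-frequency stratified McDonald-Kreitman statistics
    (fixation index, neutrality index, direction of selection, proportion of
    adaptive substitutions) with the Williams-corrected G-test, a dual
    Fisher's exact screen for human-branch evolutionary rate acceleration
    with neighbor-joining topology confirmation and rate-matched control
    sampling, functional-group comparisons of fixation-index distributions,
    and a seeded generator of codon alignments and coding polymorphism with
    known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    seqinr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
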