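Package: mitoring
Title: Structural Analysis of Circular Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Mito", "Ring", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the structural genomics of plant mitochondrial DNA:
    discovery and naming of large repeated sequences, circularization of
    assembly contigs by terminal overlap or via repeats, merging of circular
    chromosomes through recombination-like events, testing whether two
    circular genomes are structural isoforms interconvertible by
    repeat-mediated homologous recombination, detection of plastid-derived
    insertions (MTPTs), calling of C-to-U RNA editing sites from per-site
    base counts with functional-effect annotation, coding-sequence
    divergence with neighbor-joining trees, and a fully seeded
    synthetic-genome generator with machine-readable ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
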