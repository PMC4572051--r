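Package: invscan
Title: Comparative Detection of Chromosomal Inversions from Draft Assemblies
    and Genetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosomal inversions by comparative anchoring of
    draft-assembly scaffolds against a reference region and corroborates them
    genetically. Provides strand-aware unique k-mer anchoring, greedy chaining
    into synteny blocks, inversion calling with breakpoint intervals,
    reference-guided scaffold ordering into a superscaffold (AGP output),
    minimum-crossover parsimony over phase-unknown F2 genotype tables,
    recombination-fraction and suppression-of-recombination analysis, split
    alignment breakpoint localization, and in-silico PCR. Includes a
    synthetic-data generator (genome pairs with a known inversion flanked by
    inverted repeat cassettes, fragmented draft scaffolds, introgression
    lines, and simulated crosses under a Haldane meiosis model with crossover
    suppression in inversion heterozygotes) so the whole pipeline is testable
    without external assemblies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
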