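Package: fraglib
Title: One-Step Mutant Library Design with Synthesizable dsDNA Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans large protein mutant libraries built by inserting
    synthesized double-stranded DNA (dsDNA) fragments into a PCR-linearized
    plasmid via in vivo assembly (IVA) cloning. Given a plasmid (GenBank), the
    gene of interest (FASTA) and a plain-text list of desired mutations
    (point, combined, insertion, deletion), the package clusters mutations
    into the fewest or cheapest synthesizable fragment regions using
    constrained partitioning-around-medoids with an exact refinement step,
    generates codon-optimized mutant fragment sequences with Tm-constrained
    homology flanks and silent marker codons, designs plasmid-linearization
    and sequencing primers with nearest-neighbor melting temperatures and
    secondary-structure/off-target checks, and writes order-ready outputs
    (per-mutant GenBank files, a CSV order sheet, a text region map). A
    simulation module estimates design success rates for random mutation
    panels with controlled insertion, deletion, and paired-mutation lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    cluster,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
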