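Package: organellr
Title: Comparative Analysis of Annotated Organellar Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for comparative analysis of annotated organellar
    (mitochondrial and plastid) genomes, built around the workflows used in
    brown-algal (Phaeophyceae) organelle genomics. Reads and writes GenBank
    flat files with circular-coordinate handling; computes genome-architecture
    statistics (gene inventories, coding fraction, gene overlaps, intergenic
    spacers); a codon-usage-bias suite (RSCU, effective number of codons,
    ENC-GC3 expected curve, neutrality regression, PR2 coordinates, delta-RSCU
    optimal codons); homology-guided C-to-U RNA-editing prediction with
    hydropathy classification; SSR, tandem and dispersed repeat detection;
    hierarchical diagnostic-SNP identification with synonymous/non-synonymous
    partitioning; pairwise Ka/Ks by the LWL and MLWL counting methods; and
    light phylogenetic summaries (p-distance, neighbor joining, RSCU
    clustering). A seeded synthetic-genome generator provides truth-known
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
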