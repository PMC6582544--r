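Package: sixmaTrans
Title: DNA 6mA Methylation Density and DNA-to-RNA Variant Transmission Analysis
Version: 0.1.0
Authors@R: person("sixmaTrans", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrative analysis linking DNA N6-methyladenine (6mA) sites to
    DNA variants, RNA variants, and variants transmitted from DNA to RNA.
    Computes 6mA/A density over scaffolds, genes, exon groups and metagene
    bins; applies the coverage filter to kinetics-derived 6mA calls; counts
    IUPAC motif coverage of site flanks; classifies DNA-to-RNA genotype
    transitions into the six transmission types; compares variant densities
    between modified and unmodified genes; and fits the 6mA-density linear
    model on per-gene transmission-type counts. Ships a deterministic
    synthetic-data generator (FASTA, GFF3, 6mA GFF, DNA/RNA VCF, callable BED,
    truth tables) so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
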