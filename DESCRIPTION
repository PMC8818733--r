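Package: bsamap
Title: Bulked Segregant Analysis Mapping of EMS-Induced Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mapping-by-sequencing toolkit for forward genetics with
    chemically mutagenized (EMS) plant populations. Provides a pedigree and
    sequencing simulator that generates two-bulk VCFs with known ground
    truth (toy genomes, EMS and background variants, backcross/selfing
    schemes, phenotype-selected bulks), the allele-frequency SNP filter
    cascade used in bulked segregant analysis (bulk allele frequencies,
    EMS canonicality, genotype quality and depth, variant impact), a
    lightweight gene-model-aware effect annotator (codon and amino-acid
    change, impact class), chromosome-wide allele-frequency scans, and the
    accompanying phenotype statistics (andromonoecy index, segregation
    chi-square, genotype-phenotype co-segregation, 2^-delta-delta-Ct
    relative expression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
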