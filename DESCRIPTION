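Package: yseqpanel
Title: Sequence-Based Y-Chromosome Panel Genotyping and Mutation-Rate
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotyping toolkit for massively parallel amplicon sequencing
    panels on the human Y chromosome. Calls sequence-based Y-STR alleles
    from paired-end FASTQ reads (anchor-based read assignment, repeat
    structure decomposition into prefix/repeat/suffix, stutter filtering,
    paired-end consensus), calls Y-SNPs with read-depth, base-quality and
    majority-fraction thresholds and assigns the deepest supported
    subhaplogroup on a phylogenetic tree, estimates per-locus microsatellite
    mutation rates from genealogical pairs with exact Clopper-Pearson
    confidence intervals and parsimony step counting for multi-copy loci,
    and summarises population diversity (discrimination capacity, allele
    frequencies, haplogroup coverage). Includes a synthetic-read and
    pedigree simulator with truth files so the whole pipeline can be
    exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
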