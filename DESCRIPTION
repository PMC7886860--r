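Package: crasskit
Title: Discovery and Annotation of crAss-Like Phage Genomes from Metagenomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of a discovery-and-annotation
    pipeline for crAss-like bacteriophages in human gut metagenomes: detection
    of circular metagenome-assembled genomes (cMAGs) by exact terminal direct
    repeats, marker-protein detection with position-specific scoring profiles
    and empirically calibrated significance, inference of alternative genetic
    codes (TAG reassigned to glutamine or TGA to tryptophan) from in-frame stop
    codons in conserved marker genes, code-aware ORF calling, split-gene
    (group I intron and intein) detection, suppressor tRNA classification,
    species-level linkage clustering of genomes, CRISPR-spacer and protein-match
    host assignment with taxonomy verification, k-mer LCA read classification
    with abundance redistribution, and pangenome rarefaction. A synthetic
    community generator plants every signal the pipeline detects, with
    serialized ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
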