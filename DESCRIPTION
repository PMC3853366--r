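Package: nanocager
Title: Processing, Filtering and Simulation of nanoCAGE 5' Tag Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of nanoCAGE libraries, in which
    template-switching oligonucleotides attach 5' adapters to cDNA so that
    transcription start sites can be mapped and quantified from single
    sequencing tags. The package parses the template-switching read layout
    (sample barcode, unique molecular identifier, TATAGGG linker), removes
    oligonucleotide artifacts and ribosomal RNA contamination using a
    bit-parallel approximate string matcher, post-filters alignments for
    strand-invasion artifacts by comparing the genomic sequence upstream of
    each tag with the 3' end of the template-switching oligo, clusters tag
    5' ends into CAGE transcription start sites, annotates clusters against
    gene models (promoter, exon, intron, other), and computes digital
    expression statistics (tags per million, rarefaction, detected and
    common loci, gene-wise correlations). A synthetic-data generator
    produces toy genomes, annotation and barcoded FASTQ libraries with
    per-read ground truth, so the whole pipeline can be validated end to
    end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomicAlignments,
    BiocGenerics,
    Rsamtools,
    rtracklayer,
    jsonlite,
    vegan,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
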