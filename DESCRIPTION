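Package: polycap
Title: Variant Discovery from Exon Capture in Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering sequence variants in allotetraploid genomes
    re-sequenced by cDNA-based exon capture with short single-end reads.
    Distinguishes fixed inter-genomic divergence between homoeologous
    subgenomes (genome-specific sites) from lineage-specific SNPs, filters
    artifacts caused by paralog alignment using allele depth-ratio
    calibration, detects copy-number and presence/absence variation from
    windowed coverage ratios and variant-pattern evidence, and annotates
    coding effects of classified sites. Includes a deterministic synthetic
    allotetraploid simulator (two diverged subgenomes, two accessions,
    capture-style 40-bp reads with divergence-dependent capture bias and
    full ground truth), a bowtie-like unique-alignment mini-aligner with
    iterative trim-and-realign rescue of exon junction reads, and
    assay design quality metrics (GC screen, 32-mer abundance index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
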