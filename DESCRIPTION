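Package: snpmine
Title: Transcriptome SNP Mining from Read Pileups on Assembled Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers putative single-nucleotide polymorphisms in a de novo
    transcriptome assembly from read-to-contig alignments. Builds per-position
    allele counts (a pileup) from a restricted SAM dialect, applies a filter
    cascade designed for 454 pyrosequencing data (read depth, minor-allele
    evidence, inter-SNP spacing against homopolymer artifacts, flanking
    sequence length, and repeat-mask read eligibility), classifies sites as
    transitions or transversions, assigns exon status and codon position from
    translated protein alignments with an all-alignments-agree rule, and
    reports per-contig, per-isogroup and density summary statistics. Includes
    a ground-truthed simulator of 454-like reads over assembler-like contigs
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
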