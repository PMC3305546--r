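#!/usr/bin/env Rscript
# Step 3 — substitution class and codon-position annotation.
#
# Classifies each accepted SNP as transition or transversion and, from the
# translated protein alignments of its contig, assigns exon status and
# codon position under the all-alignments-agree rule (covering alignments
# that disagree make the position "uncertain").

library(snpmine)

contigs <- read_masked_fasta("results/sim/contigs.fasta")
blast <- read_blast_tabular("results/sim/blast.tsv")
iso <- read_isogroup_map("results/sim/isogroups.tsv")
acc <- read.delim("results/accepted_candidates.tsv",
                  stringsAsFactors = FALSE)

rows <- annotate_snps(acc, blast = blast, isogroup_map = iso)
write_snp_table(rows, "results/snp_table.tsv", contigs = contigs)

cat(sprintf("annotated %d SNPs -> results/snp_table.tsv\n", nrow(rows)))
cat(sprintf("  transitions %d / transversions %d\n",
            sum(rows$class == "transition"),
            sum(rows$class == "transversion")))
cat(sprintf("  exonic %d (codon pos 1: %d, 2: %d, 3: %d, uncertain: %d)\n",
            sum(rows$exon_status == "exonic"),
            sum(rows$codon_position == "1"),
            sum(rows$codon_position == "2"),
            sum(rows$codon_position == "3"),
            sum(rows$codon_position == "uncertain")))
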