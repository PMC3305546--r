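#!/usr/bin/env Rscript
# Step 2 — pileup and filter cascade.
#
# Reads the simulated contigs and alignments, drops repeat-dominated reads
# (no 100 bp unmasked run), builds the per-position allele counts, and
# applies the filter cascade: depth >= 5, minor allele >= 2, biallelic
# only, >= 50 bp between surviving sites, >= 25 bp flanks. Writes the
# accepted candidates and the per-filter audit.

library(snpmine)

contigs <- read_masked_fasta("results/sim/contigs.fasta")
aln <- read_alignments("results/sim/reads.sam", contigs)
cfg <- snp_config()

eligible <- filter_eligible_reads(aln, cfg$min_unmasked_run)
cat(sprintf("reads: %d mapped, %d ineligible (repeat-dominated)\n",
            nrow(aln), attr(eligible, "n_ineligible")))

pile <- build_pileup(eligible, contigs, cfg$min_contig_len)
res <- run_filter_cascade(pile, contigs, cfg, verbose = TRUE)

dir.create("results", showWarnings = FALSE)
write.table(res$snps, "results/accepted_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
audit <- data.frame(stage = names(res$audit), count = as.integer(res$audit))
write.table(audit, "results/filter_audit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("accepted %d of %d candidate sites -> results/accepted_candidates.tsv\n",
            res$audit[["accepted"]], res$audit[["candidates"]]))
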