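#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study data set.
#
# Produces a ground-truthed stand-in for a normalized 454 transcriptome
# experiment: assembler-like contigs with repeat-mask runs, planted
# biallelic SNPs at 2:1 Ti:Tv, pre-aligned error-bearing reads, translated
# protein alignments (a few deliberately frame-conflicting), and an
# isogroup map. All downstream steps read only the files written here.

library(snpmine)

outdir <- "results/sim"
cfg <- sim_config(n_contigs = 100, coverage = 25, n_snps = 500,
                  titv_ratio = 2, seed = 101)

sim <- generate_truth_set(cfg)
aln <- simulate_reads(sim$contigs, sim$truth, cfg)
write_simulation(sim, aln, outdir)

lens <- contig_lengths(sim$contigs)
cat(sprintf("wrote %s: %d contigs (%d bp, median %d bp), %d reads,\n",
            outdir, length(lens), sum(lens), as.integer(median(lens)),
            nrow(aln)))
cat(sprintf("  %d planted SNPs (%d ideal-survivable), %d protein alignments\n",
            nrow(sim$truth), sum(sim$truth$ideal_survivable),
            nrow(sim$blast)))
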