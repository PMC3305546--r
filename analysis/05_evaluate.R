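#!/usr/bin/env Rscript
# Step 5 — recovery against the planted truth.
#
# Because step 1 planted every SNP, the call set can be scored exactly:
# sensitivity on the ideal-survivable sites, precision over all calls, the
# recovered Ti:Tv ratio against its 99% binomial interval, and the
# planted-vs-assigned codon-position confusion matrix.

library(snpmine)

truth <- read.delim("results/sim/truth.tsv", stringsAsFactors = FALSE,
                    colClasses = c(contig_id = "character"))
rows <- read_snp_table("results/snp_table.tsv")
# the evaluator matches on the candidate fields present in the SNP table
ev <- evaluate_recovery(truth, rows)

iv <- titv_interval(ev$n_called, ratio = 2, conf = 0.99)
cat(sprintf("called %d SNPs; %d ideal-survivable planted sites\n",
            ev$n_called, ev$n_truth_survivable))
cat(sprintf("sensitivity %.3f, precision %.3f\n",
            ev$sensitivity, ev$precision))
cat(sprintf("recovered Ti:Tv %.2f (99%% interval for planted 2:1: [%.2f, %.2f])\n",
            ev$titv_estimate, iv[["lower"]], iv[["upper"]]))
cat("codon confusion (planted x assigned):\n")
print(ev$codon_confusion)

metrics <- data.frame(
  metric = c("sensitivity", "precision", "titv_estimate", "n_called",
             "n_truth_survivable"),
  value = c(ev$sensitivity, ev$precision, ev$titv_estimate, ev$n_called,
            ev$n_truth_survivable))
write.table(metrics, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/recovery.tsv\n")
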