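#' Run the full SNP-mining pipeline on loaded inputs
#'
#' Convenience composition of the stages: read eligibility filtering,
#' pileup construction, the filter cascade, and (when protein alignments
#' are supplied) transition/transversion and codon-position annotation.
#'
#' @param contigs a `masked_contigs` collection.
#' @param alignments alignment data.frame (see `read_alignments()`).
#' @param config a `snp_config`.
#' @param blast optional protein-alignment data.frame.
#' @param isogroup_map optional contig-to-isogroup data.frame.
#' @param verbose emit per-filter counts (default FALSE).
#' @return list with `snps` (annotated SNP-table rows), `audit` (filter
#'   audit counts, plus `reads_ineligible`), and `accepted` (the accepted
#'   candidates with their pileup evidence).
#' @export
call_snps <- function(contigs, alignments, config = snp_config(),
                      blast = NULL, isogroup_map = NULL, verbose = FALSE) {
  eligible <- filter_eligible_reads(alignments, config$min_unmasked_run)
  n_inelig <- attr(eligible, "n_ineligible")
  if (verbose) {
    message(sprintf("reads: %d total, %d ineligible (unmasked run < %d bp)",
                    nrow(alignments), n_inelig, config$min_unmasked_run))
  }
  pile <- build_pileup(eligible, contigs, config$min_contig_len)
  res <- run_filter_cascade(pile, contigs, config, verbose = verbose)
  rows <- annotate_snps(res$snps, blast = blast, isogroup_map = isogroup_map)
  audit <- c(res$audit, reads_ineligible = n_inelig)
  list(snps = rows, audit = audit, accepted = res$snps)
}
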