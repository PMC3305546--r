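small_cfg <- function(...) {
  args <- list(n_contigs = 15, coverage = 20, n_snps = 40, seed = 9)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("the generator is deterministic in its seed", {
  a <- generate_truth_set(small_cfg())
  b <- generate_truth_set(small_cfg())
  expect_identical(a$truth, b$truth)
  expect_identical(a$blast, b$blast)
  expect_identical(vapply(a$contigs, `[[`, character(1), "sequence"),
                   vapply(b$contigs, `[[`, character(1), "sequence"))
  ra <- simulate_reads(a$contigs, a$truth, small_cfg())
  rb <- simulate_reads(b$contigs, b$truth, small_cfg())
  expect_identical(ra, rb)
  # a different seed changes the stream
  c <- generate_truth_set(small_cfg(seed = 10))
  expect_false(identical(
    vapply(a$contigs, `[[`, character(1), "sequence"),
    vapply(c$contigs, `[[`, character(1), "sequence")))
})

test_that("degenerate configurations behave as documented", {
  # zero density: no truth records
  sim <- generate_truth_set(sim_config(n_contigs = 5, snp_density = 0,
                                       seed = 3))
  expect_identical(nrow(sim$truth), 0L)
  # zero coverage: no reads
  sim <- generate_truth_set(small_cfg())
  aln <- simulate_reads(sim$contigs, sim$truth, small_cfg(coverage = 0))
  expect_identical(nrow(aln), 0L)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, sim$contigs, f)
  back <- read_alignments(f, sim$contigs)   # header-only SAM reads back empty
  expect_identical(nrow(back), 0L)
  expect_error(sim_config(mask_fraction = 1.5), "rates")
  expect_error(sim_config(titv_ratio = 0), "titv_ratio")
})

test_that("planted truth respects alleles, classes and ORF frames", {
  sim <- generate_truth_set(small_cfg(orf_fraction = 1))
  tr <- sim$truth
  expect_true(all(tr$ref_allele != tr$alt_allele))
  expect_identical(classify_titv(tr$ref_allele, tr$alt_allele),
                   tr$planted_class)
  # the reference allele is the contig base at the site
  for (j in seq_len(nrow(tr))) {
    expect_identical(substring(sim$contigs[[tr$contig_id[j]]]$sequence,
                               tr$position[j], tr$position[j]),
                     tr$ref_allele[j])
  }
  # planted codon positions agree with the primary ORF record
  for (r in seq_len(nrow(sim$orfs))) {
    o <- sim$orfs[r, ]
    sel <- tr$contig_id == o$contig_id & tr$position >= o$orf_start &
      tr$position <= o$orf_end
    if (!any(sel)) next
    qs <- if (o$frame_sign > 0) o$orf_start else o$orf_end
    qe <- if (o$frame_sign > 0) o$orf_end else o$orf_start
    expect_identical(tr$planted_codon_position[sel],
                     as.character(codon_position_single(
                       qs, qe, o$frame_sign, tr$position[sel])))
  }
})

test_that("simulated alignments are internally consistent", {
  cfg <- small_cfg(homopolymer_indel_rate = 0.2)
  sim <- generate_truth_set(cfg)
  aln <- simulate_reads(sim$contigs, sim$truth, cfg)
  lens <- contig_lengths(sim$contigs)
  expect_gt(nrow(aln), 0)
  for (i in sample.int(nrow(aln), min(nrow(aln), 200))) {
    ops <- snpmine:::parse_cigar(aln$cigar[i])
    expect_identical(snpmine:::cigar_query_length(ops),
                     nchar(aln$seq[i]))
    end <- aln$start[i] + snpmine:::cigar_reference_span(ops) - 1L
    expect_lte(end, lens[[aln$contig_id[i]]])
  }
  # sorted stream
  expect_false(is.unsorted(order(aln$contig_id, aln$start)))
  # round trip through SAM
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, sim$contigs, f)
  back <- read_alignments(f, sim$contigs)
  expect_identical(back[, c("read_id", "contig_id", "start", "cigar")],
                   aln[, c("read_id", "contig_id", "start", "cigar")])
})

test_that("error-free recovery is perfect and evaluation handles edge cases", {
  cfg <- small_cfg(substitution_error_rate = 0, homopolymer_indel_rate = 0,
                   coverage = 25)
  sim <- generate_truth_set(cfg)
  aln <- simulate_reads(sim$contigs, sim$truth, cfg)
  res <- call_snps(sim$contigs, aln, snp_config(), blast = sim$blast)
  ev <- evaluate_recovery(sim$truth, res$snps)
  expect_identical(ev$sensitivity, 1)
  expect_identical(ev$precision, 1)
  # empty call set: sensitivity zero, precision absent
  ev0 <- evaluate_recovery(sim$truth, res$snps[0, ])
  expect_identical(ev0$sensitivity, 0)
  expect_true(is.na(ev0$precision))
})

test_that("codon recovery matches the planted phase without conflicts", {
  cfg <- small_cfg(conflicting_alignment_fraction = 0, orf_fraction = 1,
                   substitution_error_rate = 0, homopolymer_indel_rate = 0,
                   coverage = 25)
  sim <- generate_truth_set(cfg)
  aln <- simulate_reads(sim$contigs, sim$truth, cfg)
  res <- call_snps(sim$contigs, aln, snp_config(), blast = sim$blast)
  tk <- paste(sim$truth$contig_id, sim$truth$position)
  m <- match(paste(res$snps$contig_id, res$snps$position), tk)
  called <- res$snps[!is.na(m), ]
  planted <- sim$truth$planted_codon_position[m[!is.na(m)]]
  exonic <- called$exon_status == "exonic"
  expect_gt(sum(exonic), 0)
  expect_identical(called$codon_position[exonic], planted[exonic])
  expect_true(all(planted[!exonic] == "none"))
})

test_that("every exonic SNP consolidates to uncertain when all alignments conflict", {
  cfg <- small_cfg(conflicting_alignment_fraction = 1, orf_fraction = 1,
                   substitution_error_rate = 0, homopolymer_indel_rate = 0,
                   coverage = 25)
  sim <- generate_truth_set(cfg)
  aln <- simulate_reads(sim$contigs, sim$truth, cfg)
  res <- call_snps(sim$contigs, aln, snp_config(), blast = sim$blast)
  exonic <- res$snps$exon_status == "exonic"
  # conflicting duplicates cover a slightly smaller span and are only
  # planted on ORFs with room for the shift; positions inside both
  # alignments of such ORFs must all be uncertain
  inner <- rep(FALSE, nrow(res$snps))
  for (r in seq_len(nrow(sim$orfs))) {
    o <- sim$orfs[r, ]
    if (o$orf_end - o$orf_start + 1L < 3L * 22L) next
    inner <- inner | (res$snps$contig_id == o$contig_id &
                        res$snps$position >= o$orf_start + 1L &
                        res$snps$position <= o$orf_end - 2L)
  }
  expect_gt(sum(exonic & inner), 0)
  expect_true(all(res$snps$codon_position[exonic & inner] == "uncertain"))
})

test_that("the spacing filter raises precision when homopolymer errors abound", {
  cfg <- sim_config(n_contigs = 25, coverage = 25, n_snps = 30,
                    homopolymer_indel_rate = 0.5,
                    substitution_error_rate = 0, seed = 21)
  sim <- generate_truth_set(cfg)
  aln <- simulate_reads(sim$contigs, sim$truth, cfg)
  eligible <- filter_eligible_reads(aln, 100L)
  pile <- build_pileup(eligible, sim$contigs, 100L)
  with_spacing <- run_filter_cascade(pile, sim$contigs, snp_config())
  no_spacing <- run_filter_cascade(pile, sim$contigs,
                                   snp_config(min_gap = 0L))
  prec <- function(called) {
    if (nrow(called) == 0) return(NA_real_)
    evaluate_recovery(sim$truth, called)$precision
  }
  expect_gte(prec(with_spacing$snps), prec(no_spacing$snps))
  # and the errors do create clustered artifacts for spacing to remove
  expect_gt(no_spacing$audit[["accepted"]], with_spacing$audit[["accepted"]])
})

test_that("recovered Ti:Tv concentrates around the planted ratio", {
  cfg <- sim_config(n_contigs = 60, coverage = 25, n_snps = 300,
                    titv_ratio = 2, seed = 31)
  sim <- generate_truth_set(cfg)
  aln <- simulate_reads(sim$contigs, sim$truth, cfg)
  res <- call_snps(sim$contigs, aln, snp_config(), blast = sim$blast)
  ev <- evaluate_recovery(sim$truth, res$snps)
  iv <- titv_interval(ev$n_called, ratio = 2, conf = 0.99)
  expect_gte(ev$titv_estimate, iv[["lower"]])
  expect_lte(ev$titv_estimate, iv[["upper"]])
})
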