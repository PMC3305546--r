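test_that("read eligibility needs a 100 bp consecutive unmasked run", {
  expect_true(eligible_read(rep(FALSE, 120)))
  # 120 bp read whose longest unmasked run is 99
  m <- rep(FALSE, 120)
  m[100] <- TRUE
  expect_false(eligible_read(m))
  # fully unmasked but only 99 bp long
  expect_false(eligible_read(rep(FALSE, 99)))
  expect_true(eligible_read(rep(FALSE, 100)))
  # threshold is configurable
  expect_true(eligible_read(rep(FALSE, 10), min_unmasked_run = 10))
  # brute-force run-length check on random masks
  set.seed(11)
  for (i in 1:50) {
    m <- runif(150) < 0.2
    runs <- rle(!m)
    expect_identical(eligible_read(m),
                     max(c(0, runs$lengths[runs$values])) >= 100)
  }
})

test_that("filter_eligible_reads drops masked-out reads and counts them", {
  aln <- data.frame(
    read_id = c("ok", "bad"), contig_id = "c1", start = 1L,
    cigar = c("120M", "120M"),
    seq = c(strrep("A", 120),
            paste0(strrep("A", 50), strrep("a", 30), strrep("A", 40))),
    stringsAsFactors = FALSE)
  out <- filter_eligible_reads(aln, 100L)
  expect_identical(out$read_id, "ok")
  expect_identical(attr(out, "n_ineligible"), 1L)
})

pileup_contig <- function(len, id = "c1") {
  snpmine:::new_masked_contigs(list(masked_contig(
    id, paste(rep("A", len), collapse = ""), rep(FALSE, len))))
}

test_that("pileup walks CIGAR strings correctly", {
  ct <- pileup_contig(200)
  aln <- data.frame(read_id = "r1", contig_id = "c1", start = 1L,
                    cigar = "4M", seq = "ACGT", stringsAsFactors = FALSE)
  p <- build_pileup(aln, ct)
  expect_identical(p$position, 1:4)
  expect_identical(p$A, c(1L, 0L, 0L, 0L))
  expect_identical(p$C, c(0L, 1L, 0L, 0L))
  expect_identical(p$G, c(0L, 0L, 1L, 0L))
  expect_identical(p$T, c(0L, 0L, 0L, 1L))

  # disagreement stacks into one column
  aln2 <- rbind(aln, data.frame(read_id = "r2", contig_id = "c1", start = 3L,
                                cigar = "1M", seq = "T"))
  p2 <- build_pileup(aln2, ct)
  expect_identical(p2[p2$position == 3, c("G", "T", "depth")],
                   data.frame(G = 1L, T = 1L, depth = 2L, row.names = 3L))

  # deletion skips the reference position without counting
  aln3 <- data.frame(read_id = "r3", contig_id = "c1", start = 1L,
                     cigar = "2M1D2M", seq = "ACGT", stringsAsFactors = FALSE)
  p3 <- build_pileup(aln3, ct)
  expect_identical(p3$position, c(1L, 2L, 4L, 5L))

  # insertions and soft clips consume read bases only; N is ignored
  aln4 <- data.frame(read_id = "r4", contig_id = "c1", start = 5L,
                     cigar = "1S2M2I2M", seq = "GACTTNT",
                     stringsAsFactors = FALSE)
  p4 <- build_pileup(aln4, ct)
  expect_identical(p4$position, c(5L, 6L, 8L))  # N at ref pos 7 uncounted
  expect_identical(p4$depth, c(1L, 1L, 1L))
})

test_that("contigs must be strictly longer than the length threshold", {
  ct <- snpmine:::new_masked_contigs(list(
    masked_contig("len100", strrep("A", 100), rep(FALSE, 100)),
    masked_contig("len101", strrep("A", 101), rep(FALSE, 101))))
  aln <- data.frame(read_id = c("r1", "r2"),
                    contig_id = c("len100", "len101"), start = 1L,
                    cigar = "4M", seq = "ACGT", stringsAsFactors = FALSE)
  p <- build_pileup(aln, ct)
  expect_identical(unique(p$contig_id), "len101")
})

test_that("pileup rejects unsorted input", {
  ct <- pileup_contig(200)
  aln <- data.frame(read_id = c("r1", "r2"), contig_id = "c1",
                    start = c(9L, 2L), cigar = "2M", seq = "AC",
                    stringsAsFactors = FALSE)
  expect_error(build_pileup(aln, ct), "sorted")
})

test_that("pileup equals the naive per-base replay on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    ct <- random_contigs(3)
    lens <- contig_lengths(ct)
    n_reads <- sample(5:20, 1)
    recs <- lapply(seq_len(n_reads), function(i) {
      cid <- sample(names(ct), 1)
      ops <- c()
      rlen <- 0L
      qlen <- 0L
      # random CIGAR from the supported dialect, anchored by an M block
      for (blk in seq_len(sample(1:4, 1))) {
        op <- if (blk == 1) "M" else sample(c("M", "I", "D", "S"), 1)
        n <- sample(1:10, 1)
        ops <- c(ops, paste0(n, op))
        if (op %in% c("M", "D")) rlen <- rlen + n
        if (op %in% c("M", "I", "S")) qlen <- qlen + n
      }
      start <- sample.int(max(1L, lens[[cid]] - rlen), 1)
      data.frame(read_id = sprintf("r%02d", i), contig_id = cid,
                 start = start, cigar = paste(ops, collapse = ""),
                 seq = paste(sample(c("A", "C", "G", "T", "N"), qlen,
                                    replace = TRUE,
                                    prob = c(rep(0.23, 4), 0.08)),
                             collapse = ""), stringsAsFactors = FALSE)
    })
    aln <- do.call(rbind, recs)
    aln <- aln[order(aln$contig_id, aln$start), ]
    got <- build_pileup(aln, ct)
    want <- oracle_pileup(aln, ct)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
    # conservation: total counts == aligned non-N read bases
    aligned <- 0L
    for (i in seq_len(nrow(aln))) {
      ex <- snpmine:::expand_alignment(aln$start[i], aln$cigar[i], aln$seq[i])
      keep <- ex$base %in% c("A", "C", "G", "T") &
        contig_lengths(ct)[[aln$contig_id[i]]] > 100
      aligned <- aligned + sum(keep)
    }
    expect_identical(sum(got$depth), as.integer(aligned))
  }
})

test_that("pileup is deterministic", {
  set.seed(5)
  ct <- random_contigs(2)
  aln <- data.frame(read_id = c("r1", "r2"), contig_id = names(ct)[1],
                    start = c(1L, 5L), cigar = c("20M", "20M"),
                    seq = c(strrep("ACGT", 5), strrep("GTCA", 5)),
                    stringsAsFactors = FALSE)
  expect_identical(build_pileup(aln, ct), build_pileup(aln, ct))
})

test_that("pileup matches Rsamtools on a converted BAM", {
  skip_if_not_installed("Rsamtools")
  set.seed(77)
  ct <- random_contigs(2, len_range = c(150L, 250L))
  lens <- contig_lengths(ct)
  recs <- lapply(1:30, function(i) {
    cid <- sample(names(ct), 1)
    rlen <- sample(20:60, 1)
    start <- sample.int(lens[[cid]] - rlen, 1)
    data.frame(read_id = sprintf("r%02d", i), contig_id = cid,
               start = start, cigar = paste0(rlen, "M"),
               seq = paste(sample(c("A", "C", "G", "T"), rlen, TRUE),
                           collapse = ""), stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, recs)
  aln <- aln[order(aln$contig_id, aln$start, aln$read_id), ]
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, ct, sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, withr::local_tempfile(),
                                           overwrite = TRUE))
  pp <- Rsamtools::PileupParam(max_depth = 1000, min_base_quality = 0,
                               min_mapq = 0, min_nucleotide_depth = 1,
                               distinguish_strands = FALSE,
                               include_deletions = FALSE)
  ref <- Rsamtools::pileup(bam, pileupParam = pp)
  got <- build_pileup(aln, ct, min_contig_len = 0L)
  long <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
    sel <- got[got[[b]] > 0, c("contig_id", "position")]
    if (nrow(sel) == 0) return(NULL)
    data.frame(sel, nucleotide = b, count = got[got[[b]] > 0, b])
  }))
  long <- long[order(long$contig_id, long$position, long$nucleotide), ]
  ref <- ref[order(ref$seqnames, ref$pos, ref$nucleotide), ]
  expect_equal(long$contig_id, as.character(ref$seqnames))
  expect_equal(long$position, ref$pos)
  expect_equal(as.character(long$nucleotide), as.character(ref$nucleotide))
  expect_equal(long$count, ref$count)
})
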