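# Independent oracles the implementation is checked against. These are kept
# deliberately naive: per-base replays, all-pairs scans and
# translate-and-diff, written without reference to the package internals.

# Naive pileup: walk every alignment base by base with explicit cursors and
# count into a position-by-base table.
oracle_pileup <- function(alignments, contigs, min_contig_len = 100L) {
  lens <- snpmine::contig_lengths(contigs)
  counts <- list()  # counts[[contig]][[pos]][[base]]
  for (i in seq_len(nrow(alignments))) {
    cid <- alignments$contig_id[[i]]
    if (lens[[cid]] <= min_contig_len) next
    if (is.null(counts[[cid]])) {
      counts[[cid]] <- matrix(0L, nrow = lens[[cid]], ncol = 4,
                              dimnames = list(NULL, c("A", "C", "G", "T")))
    }
    ops <- regmatches(alignments$cigar[[i]],
                      gregexpr("[0-9]+[A-Z=]", alignments$cigar[[i]]))[[1]]
    seq <- toupper(alignments$seq[[i]])
    rpos <- alignments$start[[i]]
    qpos <- 1L
    for (tok in ops) {
      op <- substring(tok, nchar(tok))
      n <- as.integer(sub(".$", "", tok))
      for (k in seq_len(n)) {
        if (op %in% c("M", "=", "X")) {
          b <- substring(seq, qpos, qpos)
          if (b %in% c("A", "C", "G", "T")) {
            counts[[cid]][rpos, b] <- counts[[cid]][rpos, b] + 1L
          }
          rpos <- rpos + 1L
          qpos <- qpos + 1L
        } else if (op %in% c("I", "S")) {
          qpos <- qpos + 1L
        } else if (op == "D") {
          rpos <- rpos + 1L
        } else {
          stop("oracle: unexpected op ", op)
        }
      }
    }
  }
  rows <- list()
  for (cid in sort(names(counts))) {
    m <- counts[[cid]]
    depth <- rowSums(m)
    for (p in which(depth > 0L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, position = p, A = m[p, "A"], C = m[p, "C"],
        G = m[p, "G"], T = m[p, "T"], depth = as.integer(depth[[p]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(0), position = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Brute-force replay of the filter cascade on a pileup: detect columns with
# two alleles, apply the depth/minor/multiallelic rules, then the all-pairs
# spacing rule among survivors, then flanks. Returns accepted
# (contig, position) keys.
oracle_cascade <- function(pileup, contig_len, min_total = 5, min_minor = 2,
                           min_gap = 50, min_flank = 25) {
  bases <- c("A", "C", "G", "T")
  cand <- list()
  for (i in seq_len(nrow(pileup))) {
    v <- unlist(pileup[i, bases])
    o <- order(-v, bases)
    if (v[o[2]] < 1) next
    cand[[length(cand) + 1L]] <- list(
      contig = pileup$contig_id[[i]], pos = pileup$position[[i]],
      depth = sum(v), minor = v[o[2]], third = v[o[3]])
  }
  surv <- Filter(function(x) {
    x$depth >= min_total && x$minor >= min_minor && x$third < min_minor
  }, cand)
  # all-pairs spacing: both members of any close pair fail
  keep <- rep(TRUE, length(surv))
  for (i in seq_along(surv)) {
    for (j in seq_along(surv)) {
      if (i != j && surv[[i]]$contig == surv[[j]]$contig &&
          abs(surv[[i]]$pos - surv[[j]]$pos) < min_gap) {
        keep[[i]] <- FALSE
      }
    }
  }
  surv <- surv[keep]
  surv <- Filter(function(x) {
    len <- contig_len[[x$contig]]
    (x$pos - 1) >= min_flank && (len - x$pos) >= min_flank
  }, surv)
  if (length(surv) == 0L) return(character(0))
  sort(vapply(surv, function(x) paste(x$contig, x$pos), character(1)))
}

# Translate-and-diff codon oracle: build the in-frame ORF sequence (reverse
# complement for the reverse frame), substitute a different base at the
# site, translate both with Biostrings, and report which base of which
# codon changed. Returns NA when the site is outside the ORF span.
oracle_codon_position <- function(contig_seq, orf_start, orf_end, frame_sign,
                                  snp_position) {
  if (snp_position < orf_start || snp_position > orf_end) return(NA_integer_)
  sub <- substring(contig_seq, orf_start, orf_end)
  ref_base <- substring(contig_seq, snp_position, snp_position)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mut <- sub
  off <- snp_position - orf_start + 1L
  substring(mut, off, off) <- alt_base
  orient <- function(s) {
    if (frame_sign > 0) s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s1 <- orient(sub)
  s2 <- orient(mut)
  # position of the changed base in reading direction
  d <- which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  stopifnot(length(d) == 1)
  ((d - 1L) %% 3L) + 1L
}

# sanity: the translation itself changes only at the codon containing the
# changed base (used once to validate the oracle's coordinate logic)
oracle_codon_check_translation <- function(contig_seq, orf_start, orf_end,
                                           frame_sign, snp_position) {
  sub <- substring(contig_seq, orf_start, orf_end)
  ref_base <- substring(contig_seq, snp_position, snp_position)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mut <- sub
  off <- snp_position - orf_start + 1L
  substring(mut, off, off) <- alt_base
  orient <- function(s) {
    x <- Biostrings::DNAString(s)
    if (frame_sign > 0) x else Biostrings::reverseComplement(x)
  }
  aa1 <- strsplit(as.character(Biostrings::translate(
    orient(sub), if.fuzzy.codon = "X", no.init.codon = TRUE)), "")[[1]]
  aa2 <- strsplit(as.character(Biostrings::translate(
    orient(mut), if.fuzzy.codon = "X", no.init.codon = TRUE)), "")[[1]]
  d <- which(strsplit(as.character(orient(Biostrings::DNAString(sub))),
                      "")[[1]] !=
             strsplit(as.character(orient(Biostrings::DNAString(mut))),
                      "")[[1]])
  codon_idx <- ((d - 1L) %/% 3L) + 1L
  all(aa1[-codon_idx] == aa2[-codon_idx])
}

# random small contig set for property tests
random_contigs <- function(n, len_range = c(120L, 400L)) {
  recs <- lapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1L)
    snpmine::masked_contig(sprintf("rc%03d", i),
                           paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = ""),
                           rep(FALSE, len))
  })
  snpmine:::new_masked_contigs(recs)
}

# random pileup columns over a contig set (not derived from reads)
random_pileup <- function(contigs, n_cols_per_contig = 6L,
                          max_count = 12L) {
  lens <- snpmine::contig_lengths(contigs)
  rows <- list()
  for (cid in names(contigs)) {
    pos <- sort(sample.int(lens[[cid]], min(n_cols_per_contig, lens[[cid]])))
    for (p in pos) {
      v <- as.integer(stats::rpois(4, lambda = sample(c(0.3, 1, 3), 1)))
      v <- pmin(v, max_count)
      if (sum(v) == 0L) v[sample.int(4, 1L)] <- 1L
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, position = p, A = v[1], C = v[2], G = v[3],
        T = v[4], depth = sum(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
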