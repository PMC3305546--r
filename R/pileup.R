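#' Read eligibility under the repeat-mask rule
#'
#' A read enters the pileup only if it contains at least
#' `min_unmasked_run` consecutive unmasked bases; reads consisting mostly of
#' repeat-masked sequence are discarded wholesale (the rule is per read, not
#' per base — once eligible, all of a read's bases count).
#'
#' @param mask logical vector over read bases, TRUE = masked.
#' @param min_unmasked_run minimum run length in bp (default 100).
#' @return TRUE iff the read is eligible.
#' @export
eligible_read <- function(mask, min_unmasked_run = 100L) {
  if (length(mask) == 0L) return(FALSE)
  r <- rle(!mask)
  any(r$values & r$lengths >= min_unmasked_run)
}

#' Drop ineligible reads from an alignment set
#'
#' Masks are derived from read sequence case (lowercase/N = masked).
#'
#' @param alignments alignment data.frame (see `read_alignments()`).
#' @param min_unmasked_run minimum unmasked run in bp.
#' @return the eligible subset, order preserved; the number removed is
#'   attached as attribute `n_ineligible`.
#' @export
filter_eligible_reads <- function(alignments, min_unmasked_run = 100L) {
  if (nrow(alignments) == 0L) {
    attr(alignments, "n_ineligible") <- 0L
    return(alignments)
  }
  keep <- vapply(alignments$seq, function(s) {
    eligible_read(read_mask_from_seq(s), min_unmasked_run)
  }, logical(1), USE.NAMES = FALSE)
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ineligible") <- sum(!keep)
  out
}

# Expand one alignment into (reference position, read base) pairs for the
# reference-consuming aligned ops. Insertions advance the read only,
# deletions the reference only, soft clips the read only.
expand_alignment <- function(start, cigar, seq) {
  ops <- parse_cigar(cigar)
  rpos <- start
  qpos <- 1L
  pos <- integer(0)
  qidx <- integer(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[[i]]
    len <- ops$len[[i]]
    if (op %in% c("M", "=", "X")) {
      pos <- c(pos, rpos:(rpos + len - 1L))
      qidx <- c(qidx, qpos:(qpos + len - 1L))
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op == "D") {
      rpos <- rpos + len
    } else {
      stop("unsupported CIGAR op '", op, "'")
    }
  }
  base <- strsplit(toupper(seq), "", fixed = TRUE)[[1]][qidx]
  list(pos = pos, base = base)
}

#' Build per-position allele counts from read alignments
#'
#' For every reference-consuming aligned base, the read base (uppercased)
#' increments the count of its allele at that contig position. Insertions
#' consume read bases without touching any column, deletions consume
#' reference positions without adding counts, soft clips are ignored, and
#' `N` bases are ignored. Contigs not strictly longer than `min_contig_len`
#' contribute no columns, and zero-depth columns are omitted.
#'
#' @param alignments alignment data.frame sorted by (contig, start); pass
#'   through `filter_eligible_reads()` first.
#' @param contigs a `masked_contigs` collection.
#' @param min_contig_len contigs must be longer than this (bp, default 100).
#' @return data.frame with columns `contig_id`, `position`, `A`, `C`, `G`,
#'   `T`, `depth`, ordered by (contig_id, position).
#' @export
build_pileup <- function(alignments, contigs, min_contig_len = 100L) {
  stopifnot(inherits(contigs, "masked_contigs"))
  if (nrow(alignments) > 0) {
    o <- order(alignments$contig_id, alignments$start)
    if (!identical(alignments$contig_id, alignments$contig_id[o]) ||
        !identical(alignments$start, alignments$start[o])) {
      stop("alignments must be sorted by (contig_id, start)")
    }
  }
  lens <- contig_lengths(contigs)
  keep_contig <- names(lens)[lens > min_contig_len]
  aln <- alignments[alignments$contig_id %in% keep_contig, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty_pileup())
  pieces <- lapply(split(seq_len(nrow(aln)), aln$contig_id), function(idx) {
    cid <- aln$contig_id[idx[[1]]]
    len <- lens[[cid]]
    pos <- integer(0)
    base <- character(0)
    for (i in idx) {
      ex <- expand_alignment(aln$start[[i]], aln$cigar[[i]], aln$seq[[i]])
      pos <- c(pos, ex$pos)
      base <- c(base, ex$base)
    }
    bidx <- match(base, c("A", "C", "G", "T"))
    ok <- !is.na(bidx)
    cnt <- tabulate((pos[ok] - 1L) * 4L + bidx[ok], nbins = 4L * len)
    m <- matrix(cnt, nrow = 4L)
    depth <- colSums(m)
    at <- which(depth > 0L)
    data.frame(contig_id = cid, position = at,
               A = m[1L, at], C = m[2L, at], G = m[3L, at], T = m[4L, at],
               depth = as.integer(depth[at]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[order(names(pieces))])
  rownames(out) <- NULL
  out
}

empty_pileup <- function() {
  data.frame(contig_id = character(0), position = integer(0),
             A = integer(0), C = integer(0), G = integer(0), T = integer(0),
             depth = integer(0), stringsAsFactors = FALSE)
}
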