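#' @keywords internal
#' Parse a CIGAR string into (op, len) pairs.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    stop("missing CIGAR string")
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHPX=]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  data.frame(op = substring(toks, nchar(toks)),
             len = as.integer(sub(".$", "", toks)),
             stringsAsFactors = FALSE)
}

cigar_query_length <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
}

cigar_reference_span <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
}

#' Read read-to-contig alignments from SAM
#'
#' Accepts the restricted alignment dialect the pipeline consumes: CIGAR
#' operations M/=/X (aligned bases), I (insertion), D (deletion) and S
#' (soft clip) only. Unmapped records are skipped; records with N/H/P
#' operations, an unknown reference, a CIGAR/sequence length mismatch, or a
#' reference span extending past the contig end are rejected with an error
#' naming the record. Per-read masks follow the same convention as contigs:
#' lowercase read bases are masked.
#'
#' @param path SAM file with `@SQ` header lines.
#' @param contigs a `masked_contigs` collection the alignments refer to.
#' @return data.frame with columns `read_id`, `contig_id`, `start` (1-based),
#'   `cigar`, `seq` (case preserved), sorted by (contig_id, start, read_id).
#' @export
read_alignments <- function(path, contigs) {
  stopifnot(inherits(contigs, "masked_contigs"))
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  lens <- contig_lengths(contigs)
  for (h in hdr[startsWith(hdr, "@SQ")]) {
    fields <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", grep("^SN:", fields, value = TRUE))
    ln <- as.integer(sub("^LN:", "", grep("^LN:", fields, value = TRUE)))
    if (length(sn) == 1 && length(ln) == 1 && sn %in% names(lens) &&
        lens[[sn]] != ln) {
      stop("SAM header @SQ length for '", sn, "' (", ln,
           ") disagrees with contig length (", lens[[sn]], ")")
    }
  }
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(empty_alignments())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  recs <- lapply(fields, function(f) {
    if (length(f) < 11L) stop("truncated SAM record: ", paste(f, collapse = " "))
    flag <- as.integer(f[[2]])
    if (bitwAnd(flag, 4L) != 0L || f[[3]] == "*") return(NULL)  # unmapped
    read_id <- f[[1]]
    contig_id <- f[[3]]
    if (!contig_id %in% names(lens)) {
      stop("read '", read_id, "': unknown reference '", contig_id, "'")
    }
    ops <- parse_cigar(f[[6]])
    bad <- intersect(ops$op, c("N", "H", "P"))
    if (length(bad) > 0) {
      stop("read '", read_id, "': unsupported CIGAR op(s) ",
           paste(bad, collapse = ","), " in ", f[[6]])
    }
    start <- as.integer(f[[4]])
    if (is.na(start) || start < 1L) {
      stop("read '", read_id, "': invalid POS ", f[[4]])
    }
    seq <- f[[10]]
    if (seq == "*") stop("read '", read_id, "': missing SEQ")
    if (cigar_query_length(ops) != nchar(seq)) {
      stop("read '", read_id, "': CIGAR query length ",
           cigar_query_length(ops), " != sequence length ", nchar(seq))
    }
    end <- start + cigar_reference_span(ops) - 1L
    if (end > lens[[contig_id]]) {
      stop("read '", read_id, "': alignment [", start, ",", end,
           "] extends past end of contig '", contig_id, "' (",
           lens[[contig_id]], " bp)")
    }
    data.frame(read_id = read_id, contig_id = contig_id, start = start,
               cigar = f[[6]], seq = seq, stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) return(empty_alignments())
  aln <- do.call(rbind, recs)
  aln <- aln[order(aln$contig_id, aln$start, aln$read_id, aln$cigar), ,
             drop = FALSE]
  rownames(aln) <- NULL
  aln
}

empty_alignments <- function() {
  data.frame(read_id = character(0), contig_id = character(0),
             start = integer(0), cigar = character(0), seq = character(0),
             stringsAsFactors = FALSE)
}

#' Write alignments to SAM
#'
#' Emits `@HD`/`@SQ` headers for every contig and one mapped record per
#' alignment row. Read case is preserved (lowercase = masked).
#'
#' @param alignments data.frame as returned by `read_alignments()`.
#' @param contigs a `masked_contigs` collection (for `@SQ` headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  stopifnot(inherits(contigs, "masked_contigs"))
  lens <- contig_lengths(contigs)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  body <- character(0)
  if (nrow(alignments) > 0) {
    body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    alignments$read_id, alignments$contig_id,
                    alignments$start, alignments$cigar, alignments$seq)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-base mask of a read from its sequence case
#'
#' @param seq read sequence as stored in the alignment (mixed case).
#' @return logical vector, TRUE where the base is masked (lowercase or N).
#' @export
read_mask_from_seq <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch %in% c("a", "c", "g", "t", "n", "N")
}
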