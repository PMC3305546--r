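#' Read translated-alignment records from BLAST tabular output
#'
#' Parses the 12-column `outfmt 6` dialect with an optional 13th frame
#' column. Query coordinates are 1-based nucleotide positions on the contig
#' or isotig; for a hit on the reverse frame `qstart > qend`. The frame sign
#' is taken from the explicit frame column when present, otherwise inferred
#' from the coordinate order. HSPs whose nucleotide span is not a multiple
#' of three cannot anchor a reading frame and are rejected with a warning;
#' the number rejected is attached as attribute `n_rejected`.
#'
#' @param path tab-separated BLAST output (`-outfmt 6`, optionally + frame).
#' @return data.frame with columns `query_id`, `subject_id`, `query_start`,
#'   `query_end`, `evalue`, `frame_sign`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0L) return(empty_blast())
  if (!ncol(raw) %in% c(12L, 13L)) {
    stop("expected 12 or 13 tab-separated columns, found ", ncol(raw))
  }
  qstart <- as.integer(raw[[7]])
  qend <- as.integer(raw[[8]])
  if (anyNA(qstart) || anyNA(qend)) {
    stop("non-integer query coordinates in ", path)
  }
  if (any(qstart == qend)) {
    stop("query_start == query_end in ", path)
  }
  frame_sign <- ifelse(qstart < qend, 1L, -1L)
  if (ncol(raw) == 13L) {
    fr <- as.integer(raw[[13]])
    if (anyNA(fr) || any(fr == 0L)) stop("invalid frame column in ", path)
    frame_sign <- as.integer(sign(fr))
  }
  evalue <- as.numeric(raw[[11]])
  if (anyNA(evalue) || any(evalue < 0)) stop("invalid evalue column in ", path)
  span <- abs(qend - qstart) + 1L
  ok <- span %% 3L == 0L
  if (any(!ok)) {
    warning(sum(!ok), " record(s) rejected: nucleotide span not a multiple of 3")
  }
  out <- data.frame(query_id = as.character(raw[[1]])[ok],
                    subject_id = as.character(raw[[2]])[ok],
                    query_start = qstart[ok], query_end = qend[ok],
                    evalue = evalue[ok], frame_sign = frame_sign[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!ok)
  out
}

empty_blast <- function() {
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    query_start = integer(0), query_end = integer(0),
                    evalue = numeric(0), frame_sign = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- 0L
  out
}

#' Write protein-alignment records as 12-column BLAST tabular
#'
#' The inverse of `read_blast_tabular()` for the fields the pipeline uses;
#' the remaining standard columns are filled with placeholder statistics.
#'
#' @param blast data.frame as returned by `read_blast_tabular()`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(blast, path) {
  n <- nrow(blast)
  aa <- (abs(blast$query_end - blast$query_start) + 1L) %/% 3L
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
                   blast$query_id, blast$subject_id, rep(95, n), aa,
                   rep(0L, n), rep(0L, n),
                   blast$query_start, blast$query_end,
                   rep(1L, n), aa, blast$evalue, 2 * aa)
  writeLines(lines, path)
  invisible(path)
}
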