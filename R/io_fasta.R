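#' Masked contig collections
#'
#' Contigs are stored with an explicit per-base repeat-mask flag recovered
#' from FASTA case: lowercase bases (RepeatMasker soft masking) are masked,
#' and `N` bases (hard masking) are treated as masked too. Sequences are held
#' uppercase; the mask is a parallel logical vector.
#'
#' @param contig_id character id, unique within a collection.
#' @param sequence uppercase nucleotide string (A/C/G/T/N).
#' @param mask logical vector, one flag per base, TRUE = repeat-masked.
#' @param isogroup_id optional isogroup (gene-level) membership.
#' @return a `masked_contig` record (a named list).
#' @export
masked_contig <- function(contig_id, sequence, mask,
                          isogroup_id = NA_character_) {
  if (!nzchar(sequence)) {
    stop("contig '", contig_id, "': empty sequence")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("contig '", contig_id, "': sequence contains non-ACGTN characters")
  }
  if (length(mask) != nchar(sequence)) {
    stop("contig '", contig_id, "': mask length != sequence length")
  }
  structure(list(contig_id = contig_id, sequence = sequence,
                 mask = as.logical(mask),
                 isogroup_id = isogroup_id),
            class = "masked_contig")
}

new_masked_contigs <- function(records) {
  ids <- vapply(records, `[[`, character(1), "contig_id")
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(records) <- ids
  structure(records, class = c("masked_contigs", "list"))
}

#' Read soft-masked contigs from FASTA
#'
#' Lowercase input bases become `mask = TRUE` and are uppercased in the
#' stored sequence; `N` (either case) is also flagged masked, so hard-masked
#' input is accepted. Record order is preserved; duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return a `masked_contigs` collection (named list of `masked_contig`).
#' @export
read_masked_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA (line 1): expected '>' header in ", path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  recs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (!nzchar(s)) stop("contig '", ids[[i]], "': empty sequence")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    mask <- ch %in% c("a", "c", "g", "t", "n", "N")
    masked_contig(ids[[i]], s, mask)
  })
  new_masked_contigs(recs)
}

#' Write masked contigs to soft-masked FASTA
#'
#' Masked positions are emitted lowercase so that
#' `read_masked_fasta(write_masked_fasta(x))` is the identity.
#'
#' @param contigs a `masked_contigs` collection.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_masked_fasta <- function(contigs, path) {
  stopifnot(inherits(contigs, "masked_contigs"))
  seqs <- vapply(contigs, function(ct) {
    ch <- strsplit(ct$sequence, "", fixed = TRUE)[[1]]
    ch[ct$mask] <- tolower(ch[ct$mask])
    paste(ch, collapse = "")
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(contigs, `[[`, character(1), "contig_id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Contig lengths of a collection
#' @param contigs a `masked_contigs` collection.
#' @return named integer vector of lengths in bp.
#' @export
contig_lengths <- function(contigs) {
  stopifnot(inherits(contigs, "masked_contigs"))
  vapply(contigs, function(ct) nchar(ct$sequence), integer(1))
}

#' Attach isogroup membership to contigs
#'
#' @param contigs a `masked_contigs` collection.
#' @param isogroup_map data.frame with columns `contig_id`, `isogroup_id`;
#'   may be partial (unmapped contigs keep `NA`).
#' @return the collection with `isogroup_id` fields filled in.
#' @export
assign_isogroups <- function(contigs, isogroup_map) {
  stopifnot(inherits(contigs, "masked_contigs"))
  idx <- match(names(contigs), isogroup_map$contig_id)
  for (i in seq_along(contigs)) {
    if (!is.na(idx[[i]])) {
      contigs[[i]]$isogroup_id <- as.character(isogroup_map$isogroup_id[idx[[i]]])
    }
  }
  contigs
}

#' @export
print.masked_contigs <- function(x, ...) {
  len <- contig_lengths(x)
  cat(sprintf("masked_contigs: %d contigs, %d bp total, %.1f%% masked\n",
              length(x), sum(len),
              100 * sum(vapply(x, function(ct) sum(ct$mask), integer(1))) /
                max(1L, sum(len))))
  invisible(x)
}
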