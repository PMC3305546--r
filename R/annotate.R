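#' Classify an allele pair as transition or transversion
#'
#' Purine–purine (A/G) and pyrimidine–pyrimidine (C/T) substitutions are
#' transitions; all purine–pyrimidine pairs are transversions. The
#' classification is symmetric in its arguments. Vectorised.
#'
#' @param allele1,allele2 bases in A/C/G/T; element-wise pairs must differ.
#' @return character vector of "transition" / "transversion".
#' @export
classify_titv <- function(allele1, allele2) {
  a1 <- toupper(allele1)
  a2 <- toupper(allele2)
  if (any(!a1 %in% c("A", "C", "G", "T")) ||
      any(!a2 %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A, C, G or T")
  }
  if (any(a1 == a2)) stop("alleles must differ")
  pair <- paste(pmin(a1, a2), pmax(a1, a2))
  ifelse(pair %in% c("A G", "C T"), "transition", "transversion")
}

#' Codon position of a site under one translated alignment
#'
#' BLASTx HSPs begin in-frame, so the query coordinate where the alignment
#' starts is codon position 1 of its reading frame. On the forward frame the
#' anchor is the smaller query coordinate and positions advance with the
#' sequence; on the reverse frame the anchor is the larger coordinate and
#' positions advance against it. Sites outside the aligned span get `NA`.
#' Vectorised over alignments for one site, or one alignment over sites.
#'
#' @param query_start,query_end 1-based nucleotide query coordinates of the
#'   HSP (for reverse-frame hits BLAST reports `query_start > query_end`).
#' @param frame_sign +1 or -1.
#' @param snp_position 1-based position on the same query sequence.
#' @return integer vector in 1:3, or `NA` where the site is not covered.
#' @export
codon_position_single <- function(query_start, query_end, frame_sign,
                                  snp_position) {
  n <- max(length(query_start), length(query_end), length(frame_sign),
           length(snp_position))
  qs <- rep_len(query_start, n)
  qe <- rep_len(query_end, n)
  fs <- rep_len(frame_sign, n)
  sp <- rep_len(snp_position, n)
  lo <- pmin(qs, qe)
  hi <- pmax(qs, qe)
  inside <- sp >= lo & sp <= hi
  out <- ifelse(fs > 0L, ((sp - lo) %% 3L) + 1L, ((hi - sp) %% 3L) + 1L)
  out[!inside] <- NA_integer_
  as.integer(out)
}

#' Consolidate codon assignments across all alignments of one query
#'
#' Exonic status requires only that some alignment cover the site; the
#' codon position is a positive call only when every covering alignment
#' agrees. Disagreement across covering alignments yields
#' `exonic`/`uncertain`; non-covering alignments neither support nor
#' contradict.
#'
#' @param positions integer vector of per-alignment codon positions for one
#'   site, `NA` for alignments not covering it (see
#'   `codon_position_single()`).
#' @return list with `exon_status` ("exonic"/"non_exonic"),
#'   `codon_position` ("1","2","3","uncertain","not_applicable") and
#'   `n_supporting` (number of covering alignments).
#' @export
consolidate_codon <- function(positions) {
  covering <- positions[!is.na(positions)]
  if (length(covering) == 0L) {
    return(list(exon_status = "non_exonic",
                codon_position = "not_applicable",
                n_supporting = 0L))
  }
  u <- unique(covering)
  list(exon_status = "exonic",
       codon_position = if (length(u) == 1L) as.character(u) else "uncertain",
       n_supporting = length(covering))
}

#' Annotate accepted SNPs with substitution class and codon position
#'
#' Joins each accepted SNP with the translated alignments of its contig,
#' classifies the allele pair as transition/transversion, and consolidates
#' the codon-position evidence across all covering alignments.
#'
#' @param snps accepted candidates from `run_filter_cascade()`.
#' @param blast protein-alignment data.frame from `read_blast_tabular()`,
#'   or NULL (every SNP then reported non-exonic).
#' @param isogroup_map optional data.frame (`contig_id`, `isogroup_id`).
#' @return data.frame of SNP-table rows (see `write_snp_table()`), sorted
#'   by (contig_id, position).
#' @export
annotate_snps <- function(snps, blast = NULL, isogroup_map = NULL) {
  n <- nrow(snps)
  exon_status <- rep("non_exonic", n)
  codon_position <- rep("not_applicable", n)
  if (!is.null(blast) && nrow(blast) > 0 && n > 0) {
    by_query <- split(seq_len(nrow(blast)), blast$query_id)
    for (i in seq_len(n)) {
      idx <- by_query[[snps$contig_id[[i]]]]
      if (is.null(idx)) next
      pos <- codon_position_single(blast$query_start[idx],
                                   blast$query_end[idx],
                                   blast$frame_sign[idx],
                                   snps$position[[i]])
      cons <- consolidate_codon(pos)
      exon_status[[i]] <- cons$exon_status
      codon_position[[i]] <- cons$codon_position
    }
  }
  iso <- rep(NA_character_, n)
  if (!is.null(isogroup_map) && n > 0) {
    m <- match(snps$contig_id, isogroup_map$contig_id)
    iso[!is.na(m)] <- isogroup_map$isogroup_id[m[!is.na(m)]]
  }
  out <- data.frame(
    contig_id = snps$contig_id,
    position = snps$position,
    allele_major = snps$allele_major,
    allele_minor = snps$allele_minor,
    count_major = snps$count_major,
    count_minor = snps$count_minor,
    class = if (n > 0) classify_titv(snps$allele_major, snps$allele_minor)
            else character(0),
    exon_status = exon_status,
    codon_position = codon_position,
    isogroup_id = iso,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
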