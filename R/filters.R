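#' Detect candidate SNP sites in a pileup
#'
#' A column is a candidate when at least two distinct bases each have a
#' count of at least one. The two highest-count bases become the major and
#' minor alleles; at equal counts the alphabetically smaller base is major
#' (a fixed tie-break so output is deterministic). `N` and deletions never
#' form alleles.
#'
#' @param pileup data.frame from `build_pileup()`.
#' @param contigs a `masked_contigs` collection (for flank lengths).
#' @return data.frame of candidates: `contig_id`, `position`,
#'   `allele_major`, `allele_minor`, `count_major`, `count_minor`,
#'   `count_third` (highest remaining allele count), `count_other`
#'   (depth minus the two allele counts), `depth`, `flank_left`,
#'   `flank_right`.
#' @export
detect_candidates <- function(pileup, contigs) {
  stopifnot(inherits(contigs, "masked_contigs"))
  lens <- contig_lengths(contigs)
  if (nrow(pileup) == 0L) return(empty_candidates())
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileup[, bases, drop = FALSE])
  stats <- t(apply(cnt, 1L, function(v) {
    o <- order(-v, bases)
    c(o[1L], o[2L], v[o[1L]], v[o[2L]], v[o[3L]])
  }))
  is_cand <- stats[, 4L] >= 1L
  if (!any(is_cand)) return(empty_candidates())
  p <- pileup[is_cand, , drop = FALSE]
  s <- stats[is_cand, , drop = FALSE]
  len <- lens[p$contig_id]
  out <- data.frame(
    contig_id = p$contig_id,
    position = p$position,
    allele_major = bases[s[, 1L]],
    allele_minor = bases[s[, 2L]],
    count_major = as.integer(s[, 3L]),
    count_minor = as.integer(s[, 4L]),
    count_third = as.integer(s[, 5L]),
    count_other = as.integer(p$depth - s[, 3L] - s[, 4L]),
    depth = p$depth,
    flank_left = p$position - 1L,
    flank_right = as.integer(len - p$position),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(contig_id = character(0), position = integer(0),
             allele_major = character(0), allele_minor = character(0),
             count_major = integer(0), count_minor = integer(0),
             count_third = integer(0), count_other = integer(0),
             depth = integer(0), flank_left = integer(0),
             flank_right = integer(0), stringsAsFactors = FALSE)
}

#' Depth and minor-allele evidence filter
#'
#' Excludes candidates whose total component reads (full column depth) fall
#' below `min_total` or whose minor allele is supported by fewer than
#' `min_minor` reads.
#'
#' @param snps candidate data.frame from `detect_candidates()`.
#' @param min_total minimum total reads (default 5).
#' @param min_minor minimum minor-allele reads (default 2).
#' @return data.frame with logical columns `fail_depth`, `fail_minor`.
#' @export
depth_and_minor_filter <- function(snps, min_total = 5L, min_minor = 2L) {
  data.frame(fail_depth = snps$depth < min_total,
             fail_minor = snps$count_minor < min_minor)
}

#' Multiallelic-site filter
#'
#' A site is rejected when a third allele reaches the same evidence
#' threshold as the minor allele — the pipeline reports biallelic SNPs only.
#'
#' @param snps candidate data.frame from `detect_candidates()`.
#' @param min_minor evidence threshold (default 2).
#' @return logical vector, TRUE = fails (multiallelic).
#' @export
multiallelic_filter <- function(snps, min_minor = 2L) {
  snps$count_third >= min_minor
}

#' Inter-SNP spacing filter
#'
#' Candidates on the same contig closer than `min_gap` bp to another
#' surviving candidate are removed — clusters of nearby "SNPs" are the
#' signature of homopolymer-induced misalignment in 454 data. By default
#' both members of a close pair are dropped; with `drop_both = FALSE` a
#' greedy left-to-right scan keeps the earlier site.
#'
#' @param positions sorted positions of surviving candidates on one contig.
#' @param min_gap minimum pairwise distance in bp (default 50).
#' @param drop_both drop both members of a close pair (default TRUE).
#' @return logical vector parallel to `positions`, TRUE = passes.
#' @export
spacing_filter <- function(positions, min_gap = 50L, drop_both = TRUE) {
  n <- length(positions)
  if (n <= 1L) return(rep(TRUE, n))
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (drop_both) {
    d <- diff(positions)
    close_left <- c(FALSE, d < min_gap)
    close_right <- c(d < min_gap, FALSE)
    !(close_left | close_right)
  } else {
    keep <- logical(n)
    last_kept <- -Inf
    for (i in seq_len(n)) {
      if (positions[[i]] - last_kept >= min_gap) {
        keep[[i]] <- TRUE
        last_kept <- positions[[i]]
      }
    }
    keep
  }
}

#' Flanking-sequence length filter
#'
#' Accepted SNPs must have at least `min_flank` bases of contig sequence on
#' each side (needed downstream for assay/primer design).
#'
#' @param position 1-based SNP position(s).
#' @param contig_length length(s) of the harbouring contig.
#' @param min_flank minimum flank in bp (default 25).
#' @return logical vector, TRUE = passes.
#' @export
flank_filter <- function(position, contig_length, min_flank = 25L) {
  (position - 1L) >= min_flank & (contig_length - position) >= min_flank
}

#' Run the full SNP filter cascade
#'
#' Applies the filters in their fixed order: depth/minor-allele evidence
#' (with the multiallelic rule alongside), then inter-SNP spacing evaluated
#' only among the evidence-surviving candidates, then flanking length. Each
#' removed candidate is attributed to its first failing stage in the audit;
#' the order matters because a low-depth artifact does not spoil the spacing
#' of a genuine neighbour.
#'
#' @param pileup data.frame from `build_pileup()`.
#' @param contigs a `masked_contigs` collection.
#' @param config a `snp_config` (defaults = the standard thresholds).
#' @param verbose emit per-filter counts as messages (default FALSE).
#' @return list with `snps` (accepted candidates, empty `filters_failed`),
#'   `candidates` (every candidate with its `filters_failed` annotation),
#'   and `audit` (named integer vector: candidates, removals per stage,
#'   accepted).
#' @export
run_filter_cascade <- function(pileup, contigs, config = snp_config(),
                               verbose = FALSE) {
  stopifnot(inherits(config, "snp_config"))
  cand <- detect_candidates(pileup, contigs)
  n <- nrow(cand)
  fails <- vector("list", n)
  dm <- depth_and_minor_filter(cand, config$min_total, config$min_minor)
  multi <- multiallelic_filter(cand, config$min_minor)
  for (i in seq_len(n)) {
    f <- character(0)
    if (dm$fail_depth[[i]]) f <- c(f, "depth")
    if (dm$fail_minor[[i]]) f <- c(f, "minor_allele")
    if (multi[[i]]) f <- c(f, "multiallelic")
    fails[[i]] <- f
  }
  surv1 <- which(!(dm$fail_depth | dm$fail_minor | multi))

  # spacing among evidence-surviving candidates, per contig
  pass_spacing <- rep(TRUE, n)
  for (idx in split(surv1, cand$contig_id[surv1])) {
    idx <- idx[order(cand$position[idx])]
    ok <- spacing_filter(cand$position[idx], config$min_gap, config$drop_both)
    pass_spacing[idx] <- ok
  }
  for (i in surv1[!pass_spacing[surv1]]) {
    fails[[i]] <- c(fails[[i]], "spacing")
  }
  surv2 <- surv1[pass_spacing[surv1]]

  lens <- contig_lengths(contigs)
  pass_flank <- rep(TRUE, n)
  if (length(surv2) > 0) {
    pass_flank[surv2] <- flank_filter(cand$position[surv2],
                                      as.integer(lens[cand$contig_id[surv2]]),
                                      config$min_flank)
  }
  for (i in surv2[!pass_flank[surv2]]) {
    fails[[i]] <- c(fails[[i]], "flank")
  }
  accepted <- surv2[pass_flank[surv2]]

  first_fail <- vapply(fails, function(f) {
    if (length(f) == 0L) NA_character_ else f[[1L]]
  }, character(1))
  stages <- c("depth", "minor_allele", "multiallelic", "spacing", "flank")
  audit <- c(candidates = n,
             vapply(stages, function(s) sum(first_fail == s, na.rm = TRUE),
                    integer(1)),
             accepted = length(accepted))
  cand$filters_failed <- vapply(fails, paste, character(1), collapse = ";")
  snps <- cand[accepted, , drop = FALSE]
  rownames(snps) <- NULL
  if (verbose) {
    message(sprintf("candidates: %d", audit[["candidates"]]))
    for (s in stages) message(sprintf("removed by %s: %d", s, audit[[s]]))
    message(sprintf("accepted: %d", audit[["accepted"]]))
  }
  list(snps = snps, candidates = cand, audit = audit)
}
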