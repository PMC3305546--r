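#' Summarize an annotated SNP set
#'
#' Computes the per-contig, per-isogroup and density statistics reported
#' for a transcriptome SNP scan: how many contigs and isogroups carry SNPs,
#' mean and maximum SNPs per contig/isogroup, how many contigs carry
#' exactly one SNP, how many isogroups carry at least two, the
#' transition/transversion split, and SNP density as base pairs per SNP.
#' Contigs absent from the isogroup map form singleton groups of their own.
#'
#' @param rows SNP-table rows (see `annotate_snps()` / `read_snp_table()`).
#' @param isogroup_map optional data.frame (`contig_id`, `isogroup_id`);
#'   when NULL, any `isogroup_id` column in `rows` is used instead.
#' @param total_bases denominator (bp) for the density statistic, e.g.
#'   total assembled contig bases; NULL leaves the density unreported.
#' @return list of class `snp_summary`.
#' @export
summarize_snps <- function(rows, isogroup_map = NULL, total_bases = NULL) {
  n <- nrow(rows)
  if (n == 0L) {
    out <- list(n_snps = 0L, n_contigs_with_snp = 0L,
                n_isogroups_with_snp = 0L,
                mean_snps_per_contig = NA_real_,
                mean_snps_per_isogroup = NA_real_,
                max_per_contig = 0L, max_per_isogroup = 0L,
                n_contigs_exactly_one = 0L, n_isogroups_at_least_two = 0L,
                bp_per_snp = NA_real_, n_transitions = 0L,
                n_transversions = 0L, total_bases = total_bases)
    return(structure(out, class = c("snp_summary", "list")))
  }
  per_contig <- table(rows$contig_id)
  iso <- rep(NA_character_, n)
  if (!is.null(isogroup_map)) {
    m <- match(rows$contig_id, isogroup_map$contig_id)
    iso[!is.na(m)] <- isogroup_map$isogroup_id[m[!is.na(m)]]
  } else if ("isogroup_id" %in% names(rows)) {
    iso <- rows$isogroup_id
  }
  # unmapped contigs act as their own (singleton) isogroup
  iso[is.na(iso)] <- paste0("contig:", rows$contig_id[is.na(iso)])
  per_iso <- table(iso)
  out <- list(
    n_snps = n,
    n_contigs_with_snp = length(per_contig),
    n_isogroups_with_snp = length(per_iso),
    mean_snps_per_contig = n / length(per_contig),
    mean_snps_per_isogroup = n / length(per_iso),
    max_per_contig = as.integer(max(per_contig)),
    max_per_isogroup = as.integer(max(per_iso)),
    n_contigs_exactly_one = sum(per_contig == 1L),
    n_isogroups_at_least_two = sum(per_iso >= 2L),
    bp_per_snp = if (is.null(total_bases)) NA_real_ else total_bases / n,
    n_transitions = sum(rows$class == "transition"),
    n_transversions = sum(rows$class == "transversion"),
    total_bases = total_bases
  )
  structure(out, class = c("snp_summary", "list"))
}

#' @export
print.snp_summary <- function(x, ...) {
  fmt1 <- function(v) if (is.na(v)) "-" else format(round(v, 1), nsmall = 1)
  cat("SNP summary\n")
  cat(sprintf("  putative SNPs:             %d\n", x$n_snps))
  cat(sprintf("  transitions/transversions: %d / %d\n",
              x$n_transitions, x$n_transversions))
  cat(sprintf("  contigs with a SNP:        %d (mean %s per contig, max %d)\n",
              x$n_contigs_with_snp, fmt1(x$mean_snps_per_contig),
              x$max_per_contig))
  cat(sprintf("  contigs with exactly one:  %d\n", x$n_contigs_exactly_one))
  cat(sprintf("  isogroups with a SNP:      %d (mean %s per isogroup, max %d)\n",
              x$n_isogroups_with_snp, fmt1(x$mean_snps_per_isogroup),
              x$max_per_isogroup))
  cat(sprintf("  isogroups with >= 2 SNPs:  %d\n", x$n_isogroups_at_least_two))
  if (!is.na(x$bp_per_snp)) {
    cat(sprintf("  one SNP every:             %.0f bp\n", x$bp_per_snp))
  }
  invisible(x)
}

#' Convert a summary to a two-column data.frame
#' @param summary a `snp_summary`.
#' @return data.frame with columns `statistic`, `value`.
#' @export
summary_as_table <- function(summary) {
  keep <- setdiff(names(summary), "total_bases")
  data.frame(statistic = keep,
             value = vapply(summary[keep], function(v) {
               if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Re-derive headline summary statistics from published SNP tables
#'
#' Reads one or more SNP tables (the format of the study's supplementary
#' SNP-discovery tables exported as TSV), recomputes the
#' transition/transversion classification from the allele pair itself
#' rather than trusting any class column, and summarizes. This is the entry
#' point for checking printed summary statistics against the deposited SNP
#' calls.
#'
#' @param paths character vector of SNP-table TSV paths.
#' @param isogroup_map optional contig-to-isogroup data.frame.
#' @param total_bases optional denominator for the density statistic (bp).
#' @return a `snp_summary`.
#' @export
rederive_published_summary <- function(paths, isogroup_map = NULL,
                                       total_bases = NULL) {
  rows <- do.call(rbind, lapply(paths, read_snp_table))
  rows$class <- classify_titv(rows$allele_major, rows$allele_minor)
  summarize_snps(rows, isogroup_map = isogroup_map, total_bases = total_bases)
}
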