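snp_table_columns <- c("contig_id", "position", "allele_major", "allele_minor",
                       "count_major", "count_minor", "class", "exon_status",
                       "codon_position", "isogroup_id")

validate_snp_rows <- function(rows, contig_len = NULL) {
  missing <- setdiff(snp_table_columns, names(rows))
  if (length(missing) > 0) {
    stop("SNP table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(rows) == 0L) return(invisible(rows))
  if (any(rows$allele_major == rows$allele_minor)) {
    stop("SNP table: allele_major == allele_minor in some row(s)")
  }
  if (any(rows$count_major < 0L | rows$count_minor < 0L)) {
    stop("SNP table: negative counts")
  }
  if (any(rows$count_major < rows$count_minor)) {
    stop("SNP table: count_major < count_minor")
  }
  if (any(rows$position < 1L)) stop("SNP table: position < 1")
  if (!is.null(contig_len)) {
    len <- contig_len[rows$contig_id]
    if (anyNA(len)) stop("SNP table: unknown contig id(s)")
    if (any(rows$position > len)) stop("SNP table: position beyond contig end")
  }
  if (!all(rows$class %in% c("transition", "transversion"))) {
    stop("SNP table: class must be transition/transversion")
  }
  if (!all(rows$exon_status %in% c("exonic", "non_exonic"))) {
    stop("SNP table: invalid exon_status")
  }
  if (!all(rows$codon_position %in% c("1", "2", "3", "uncertain",
                                      "not_applicable"))) {
    stop("SNP table: invalid codon_position")
  }
  exonic <- rows$exon_status == "exonic"
  if (any(exonic & rows$codon_position == "not_applicable") ||
      any(!exonic & rows$codon_position != "not_applicable")) {
    stop("SNP table: codon_position inconsistent with exon_status")
  }
  invisible(rows)
}

#' Write an annotated SNP table as TSV
#'
#' Rows are validated against the table invariants before anything is
#' written. The fixed header makes `read_snp_table()` after
#' `write_snp_table()` an identity.
#'
#' @param rows data.frame of annotated SNPs (see `annotate_snps()`).
#' @param path output file.
#' @param contigs optional `masked_contigs` collection; when given, SNP
#'   positions are checked against contig lengths.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(rows, path, contigs = NULL) {
  len <- if (is.null(contigs)) NULL else contig_lengths(contigs)
  validate_snp_rows(rows, len)
  utils::write.table(rows[, snp_table_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an annotated SNP table from TSV
#'
#' Requires the columns written by `write_snp_table()`; extra columns are
#' tolerated and dropped, a missing required column is an error naming it.
#'
#' @param path TSV file.
#' @return data.frame with the standard SNP-table columns.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop("SNP table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "NA")
  missing <- setdiff(snp_table_columns, names(raw))
  if (length(missing) > 0) {
    stop("SNP table ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- raw[, snp_table_columns, drop = FALSE]
  out$position <- as.integer(out$position)
  out$count_major <- as.integer(out$count_major)
  out$count_minor <- as.integer(out$count_minor)
  validate_snp_rows(out)
  out
}

#' Read a contig-to-isogroup mapping from TSV
#'
#' @param path TSV with columns `contig_id` and `isogroup_id`.
#' @return data.frame with those two character columns.
#' @export
read_isogroup_map <- function(path) {
  if (!file.exists(path)) stop("isogroup map not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(c("contig_id", "isogroup_id"), names(raw))
  if (length(missing) > 0) {
    stop("isogroup map ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$contig_id)) {
    stop("isogroup map: duplicate contig id(s)")
  }
  raw[, c("contig_id", "isogroup_id"), drop = FALSE]
}

#' Write a contig-to-isogroup mapping as TSV
#' @param map data.frame with columns `contig_id`, `isogroup_id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_isogroup_map <- function(map, path) {
  utils::write.table(map[, c("contig_id", "isogroup_id"), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
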