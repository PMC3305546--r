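#' Filter-cascade configuration
#'
#' Bundles the thresholds of the SNP filter cascade. Defaults are the values
#' used for 454 transcriptome SNP mining: a column needs at least 5 reads in
#' total and 2 reads supporting the minor allele; accepted sites must be at
#' least 50 bp from any other surviving candidate (suppressing clustered
#' homopolymer artifacts) and carry at least 25 bp of flanking sequence on
#' both sides; reads contribute only if they contain a run of at least 100
#' consecutive unmasked bases, and contigs only if longer than 100 bp.
#'
#' @param min_total minimum total read depth at a candidate column (reads).
#' @param min_minor minimum read count for the minor allele (reads). Also the
#'   evidence threshold above which a third allele marks a site multiallelic.
#' @param min_gap minimum distance in bp between surviving candidate sites on
#'   one contig; sites closer than this fail the spacing filter.
#' @param min_flank minimum flanking sequence length in bp on each side.
#' @param min_unmasked_run minimum run of consecutive unmasked bases (bp) a
#'   read must contain to enter the pileup.
#' @param min_contig_len contigs must be strictly longer than this (bp) to
#'   contribute pileup columns.
#' @param drop_both if TRUE (default) the spacing filter removes both members
#'   of a close pair; if FALSE a greedy left-to-right scan keeps the first.
#' @return a list of class `snp_config`.
#' @export
snp_config <- function(min_total = 5L, min_minor = 2L, min_gap = 50L,
                       min_flank = 25L, min_unmasked_run = 100L,
                       min_contig_len = 100L, drop_both = TRUE) {
  cfg <- list(
    min_total = as.integer(min_total),
    min_minor = as.integer(min_minor),
    min_gap = as.integer(min_gap),
    min_flank = as.integer(min_flank),
    min_unmasked_run = as.integer(min_unmasked_run),
    min_contig_len = as.integer(min_contig_len),
    drop_both = isTRUE(drop_both)
  )
  num <- cfg[setdiff(names(cfg), "drop_both")]
  if (any(vapply(num, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("snp_config: all thresholds must be non-negative integers")
  }
  structure(cfg, class = c("snp_config", "list"))
}

#' Read a filter configuration from a YAML file
#'
#' Unknown keys are rejected; absent keys keep their defaults.
#'
#' @param path YAML file with any subset of the `snp_config()` keys.
#' @return a `snp_config` list.
#' @export
read_snp_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(snp_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(snp_config, raw)
}

#' @export
print.snp_config <- function(x, ...) {
  cat("SNP filter configuration\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, x[[k]]))
  invisible(x)
}
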