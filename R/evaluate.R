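#' Evaluate SNP-call recovery against a planted truth set
#'
#' A called SNP matches a truth record when it lies on the same contig at
#' the same position and its unordered allele pair equals the planted
#' reference/alternative pair. Sensitivity is measured on the
#' ideal-survivable subset of the truth (sites the filter cascade could
#' accept on position and mask grounds); precision over all calls.
#'
#' @param truth truth data.frame from `generate_truth_set()`.
#' @param called called SNPs: accepted candidates from
#'   `run_filter_cascade()` or annotated rows from `annotate_snps()` (the
#'   latter enable the codon confusion matrix).
#' @return list with `sensitivity`, `precision` (NA when no calls),
#'   `titv_estimate` (transition/transversion ratio among calls, NA when no
#'   transversions), `n_called`, `n_truth_survivable`, `n_matched`, and
#'   `codon_confusion` (planted vs assigned codon position, when the calls
#'   carry a `codon_position` column).
#' @export
evaluate_recovery <- function(truth, called) {
  key <- function(cid, pos) paste(cid, pos, sep = ":")
  pairkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tk <- key(truth$contig_id, truth$position)
  ck <- if (nrow(called) > 0) key(called$contig_id, called$position)
        else character(0)
  m <- match(ck, tk)
  allele_ok <- !is.na(m) &
    pairkey(called$allele_major, called$allele_minor) ==
      pairkey(truth$ref_allele[ifelse(is.na(m), 1L, m)],
              truth$alt_allele[ifelse(is.na(m), 1L, m)])
  matched_truth <- unique(m[allele_ok])
  surv <- which(truth$ideal_survivable)
  sensitivity <- if (length(surv) == 0L) NA_real_ else
    length(intersect(matched_truth, surv)) / length(surv)
  precision <- if (nrow(called) == 0L) NA_real_ else
    sum(allele_ok) / nrow(called)
  titv <- NA_real_
  if (nrow(called) > 0) {
    cls <- classify_titv(called$allele_major, called$allele_minor)
    nv <- sum(cls == "transversion")
    if (nv > 0) titv <- sum(cls == "transition") / nv
  }
  confusion <- NULL
  if ("codon_position" %in% names(called) && nrow(called) > 0) {
    ok <- which(allele_ok)
    planted <- factor(truth$planted_codon_position[m[ok]],
                      levels = c("1", "2", "3", "none"))
    assigned <- factor(called$codon_position[ok],
                       levels = c("1", "2", "3", "uncertain",
                                  "not_applicable"))
    confusion <- table(planted = planted, assigned = assigned)
  }
  list(sensitivity = sensitivity, precision = precision,
       titv_estimate = titv, n_called = nrow(called),
       n_truth_survivable = length(surv),
       n_matched = length(matched_truth),
       codon_confusion = confusion)
}

#' Binomial interval for a recovered transition:transversion ratio
#'
#' Under a planted ratio r, each site is a transition with probability
#' r/(1+r); the central `conf` binomial interval on the transition count
#' among n sites maps to an interval on the observed ratio.
#'
#' @param n number of classified sites.
#' @param ratio planted transition:transversion ratio (default 2).
#' @param conf central coverage (default 0.99).
#' @return numeric vector `c(lower, upper)` of admissible observed ratios.
#' @export
titv_interval <- function(n, ratio = 2, conf = 0.99) {
  p <- ratio / (1 + ratio)
  a <- (1 - conf) / 2
  klo <- stats::qbinom(a, n, p)
  khi <- stats::qbinom(1 - a, n, p)
  c(lower = klo / (n - klo), upper = khi / (n - khi))
}
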