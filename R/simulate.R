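#' Simulation configuration for 454-like transcriptome data
#'
#' Parameterises the generator of ground-truthed inputs: assembler-like
#' contigs, planted biallelic substitution sites, pre-aligned 454-style
#' reads with homopolymer indel errors, and translated-alignment records
#' (with an optional fraction of frame-conflicting duplicates). Defaults
#' describe a normalized 454 transcriptome assembly: contig lengths
#' log-normal with median ~500 bp, ~18x read coverage, reads ~350 bp,
#' planted SNP density one per 483 bp, minor allele frequency 0.5 (the
#' heterozygous-parent case of a pooled full-sib design), transition:
#' transversion ratio 2:1, substitution error 1e-3 per base and one
#' homopolymer indel per 100 runs of length >= 3, 10% repeat-masked
#' sequence in ~150 bp runs, 45% of contigs carrying an in-frame ORF, and
#' 5% of ORF-bearing contigs receiving a conflicting frame-shifted
#' alignment.
#'
#' @param n_contigs number of contigs.
#' @param contig_len_meanlog,contig_len_sdlog log-normal parameters of the
#'   contig length distribution (bp).
#' @param gc_fraction GC content of simulated sequence.
#' @param snp_density planted SNPs per bp (ignored when `n_snps` is set).
#' @param n_snps optional total number of planted sites, allocated across
#'   contigs proportionally to length.
#' @param minor_allele_frequency per-read probability of drawing the
#'   alternative allele at a planted site; a scalar in (0, 0.5], or a
#'   function(n) returning n frequencies.
#' @param titv_ratio transition:transversion ratio among planted sites.
#' @param coverage mean read depth per base.
#' @param read_len_mean,read_len_sd,read_len_min normal read-length model
#'   (bp), truncated below at `read_len_min`.
#' @param homopolymer_indel_rate probability of one indel per homopolymer
#'   run of length >= 3 within a read.
#' @param substitution_error_rate per-base substitution error probability.
#' @param mask_fraction target fraction of repeat-masked contig sequence.
#' @param mask_run_mean mean length (bp) of a masked run.
#' @param orf_fraction fraction of (long enough) contigs carrying a
#'   simulated in-frame ORF with an alignment record.
#' @param conflicting_alignment_fraction fraction of ORF contigs that also
#'   receive a frame-shifted, conflicting alignment.
#' @param seed integer seed fixing the entire output stream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 100L,
                       contig_len_meanlog = log(500), contig_len_sdlog = 0.6,
                       gc_fraction = 0.45,
                       snp_density = 1 / 483, n_snps = NULL,
                       minor_allele_frequency = 0.5,
                       titv_ratio = 2.0,
                       coverage = 18,
                       read_len_mean = 350, read_len_sd = 100,
                       read_len_min = 50,
                       homopolymer_indel_rate = 0.01,
                       substitution_error_rate = 0.001,
                       mask_fraction = 0.10, mask_run_mean = 150,
                       orf_fraction = 0.45,
                       conflicting_alignment_fraction = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$snp_density, cfg$homopolymer_indel_rate,
             cfg$substitution_error_rate, cfg$mask_fraction,
             cfg$orf_fraction, cfg$conflicting_alignment_fraction,
             cfg$gc_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$titv_ratio <= 0) stop("titv_ratio must be > 0")
  if (cfg$coverage < 0) stop("coverage must be >= 0")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = c("sim_config", "list"))
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
transversion_partners <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

random_sequence <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

plant_mask <- function(len, mask_fraction, run_mean) {
  mask <- rep(FALSE, len)
  if (mask_fraction <= 0 || len < 2L) return(mask)
  n_runs <- stats::rpois(1L, len * mask_fraction / run_mean)
  for (k in seq_len(n_runs)) {
    rl <- 1L + stats::rgeom(1L, 1 / run_mean)
    s <- sample.int(len, 1L)
    e <- min(len, s + rl - 1L)
    mask[s:e] <- TRUE
  }
  mask
}

draw_maf <- function(maf, n) {
  if (is.function(maf)) maf(n) else rep(maf, n)
}

# Relative eligible coverage at a site: the expected number of
# mask-eligible reads covering `pos`, integrated over representative
# quantiles of the read-length distribution, divided by the value an
# unmasked interior site would get (the mean read length). Equals 1 where
# the repeat mask and the contig ends cost nothing; deterministic from the
# contig mask alone. Used for the ideal-survivability flag of planted
# sites: a site deep inside a repeat run, or close to a contig end, loses
# much of its eligible coverage and cannot be expected to pass the depth
# filters reliably.
site_eligible_fraction <- function(mask, pos, read_lens, min_run) {
  len <- length(mask)
  n_elig <- vapply(read_lens, function(L) {
    starts <- (pos - L + 1L):pos
    near <- max(1L, pos - L + 1L):min(len, pos + L - 1L)
    if (!any(mask[near])) {
      clipped <- pmin(len, starts + L - 1L) - pmax(1L, starts) + 1L
      return(sum(clipped >= min_run))
    }
    sum(vapply(starts, function(s) {
      e <- min(len, s + L - 1L)
      s <- max(1L, s)
      if (e - s + 1L < min_run) return(FALSE)
      r <- rle(!mask[s:e])
      any(r$values & r$lengths >= min_run)
    }, logical(1)))
  }, numeric(1))
  mean(n_elig) / mean(read_lens)
}

#' Generate ground-truthed contigs, planted SNPs and protein alignments
#'
#' Samples contigs with assembler-like length distribution and repeat-mask
#' runs, plants biallelic substitution sites with the configured allele
#' frequency and transition:transversion ratio, plants in-frame ORFs on a
#' fraction of contigs and emits their translated-alignment records (some
#' contigs receive a second consistent sub-alignment; a configured fraction
#' receives a frame-shifted conflicting one), and groups contigs into
#' isogroups. Each truth record carries an `ideal_survivable` flag: whether
#' the site would pass an ideal filter cascade on position and mask grounds
#' alone: contig long enough, both flanks sufficient, no planted neighbour
#' within the spacing threshold, and expected mask-eligible read coverage
#' at the site at least 90% of what an unmasked interior site receives (so
#' neither the repeat mask nor a contig end materially depletes read depth
#' there). Fully reproducible from `config$seed`.
#'
#' @param config a `sim_config`.
#' @param filters a `snp_config` used for the survivability flag.
#' @return list with `contigs` (a `masked_contigs`), `truth` (data.frame:
#'   `contig_id`, `position`, `ref_allele`, `alt_allele`,
#'   `minor_frequency`, `planted_class`, `planted_codon_position`,
#'   `ideal_survivable`), `blast` (protein-alignment data.frame),
#'   `isogroups` (contig-to-isogroup data.frame) and `orfs` (internal ORF
#'   table with `contig_id`, `orf_start`, `orf_end`, `frame_sign`).
#' @export
generate_truth_set <- function(config = sim_config(),
                               filters = snp_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_contigs
  lens <- pmax(50L, as.integer(round(stats::rlnorm(
    n, config$contig_len_meanlog, config$contig_len_sdlog))))
  ids <- sprintf("contig%05d", seq_len(n))

  contigs <- vector("list", n)
  for (i in seq_len(n)) {
    seq <- random_sequence(lens[[i]], config$gc_fraction)
    mask <- plant_mask(lens[[i]], config$mask_fraction, config$mask_run_mean)
    contigs[[i]] <- masked_contig(ids[[i]], seq, mask)
  }
  contigs <- new_masked_contigs(contigs)

  # isogroups: group sizes 1 + Poisson(1.6), mean ~2.6 contigs per group
  iso_of <- character(n)
  g <- 0L
  i <- 1L
  while (i <= n) {
    g <- g + 1L
    size <- 1L + stats::rpois(1L, 1.6)
    iso_of[i:min(n, i + size - 1L)] <- sprintf("isogroup%04d", g)
    i <- i + size
  }
  isogroups <- data.frame(contig_id = ids, isogroup_id = iso_of,
                          stringsAsFactors = FALSE)
  contigs <- assign_isogroups(contigs, isogroups)

  # ORFs and their alignment records
  orfs <- list()
  blast <- list()
  min_codons <- 20L
  for (i in seq_len(n)) {
    len <- lens[[i]]
    max_codons <- (len - 10L) %/% 3L
    if (max_codons < min_codons) next
    if (stats::runif(1L) > config$orf_fraction) next
    n_codons <- sample(min_codons:min(max_codons, 300L), 1L)
    span <- 3L * n_codons
    s <- sample.int(len - span + 1L, 1L)
    e <- s + span - 1L
    strand <- sample(c(1L, -1L), 1L)
    qs <- if (strand > 0L) s else e
    qe <- if (strand > 0L) e else s
    orfs[[length(orfs) + 1L]] <- data.frame(
      contig_id = ids[[i]], orf_start = s, orf_end = e,
      frame_sign = strand, stringsAsFactors = FALSE)
    blast[[length(blast) + 1L]] <- data.frame(
      query_id = ids[[i]], subject_id = sprintf("prot%05d", i),
      query_start = qs, query_end = qe, evalue = 1e-20,
      frame_sign = strand, stringsAsFactors = FALSE)
    conflict <- stats::runif(1L) < config$conflicting_alignment_fraction
    if (conflict && span >= 3L * (min_codons + 2L)) {
      # frame-shifted duplicate: disagrees at every covered position
      s2 <- s + 1L
      e2 <- e - 2L
      qs2 <- if (strand > 0L) s2 else e2
      qe2 <- if (strand > 0L) e2 else s2
      blast[[length(blast) + 1L]] <- data.frame(
        query_id = ids[[i]], subject_id = sprintf("prot%05dx", i),
        query_start = qs2, query_end = qe2, evalue = 1e-10,
        frame_sign = strand, stringsAsFactors = FALSE)
    } else if (stats::runif(1L) < 0.5 && span >= 3L * (min_codons + 2L)) {
      # consistent sub-alignment offset by one codon: agrees everywhere
      s2 <- s + 3L
      e2 <- e - 3L
      qs2 <- if (strand > 0L) s2 else e2
      qe2 <- if (strand > 0L) e2 else s2
      blast[[length(blast) + 1L]] <- data.frame(
        query_id = ids[[i]], subject_id = sprintf("prot%05db", i),
        query_start = qs2, query_end = qe2, evalue = 1e-15,
        frame_sign = strand, stringsAsFactors = FALSE)
    }
  }
  orfs <- if (length(orfs) > 0) do.call(rbind, orfs) else
    data.frame(contig_id = character(0), orf_start = integer(0),
               orf_end = integer(0), frame_sign = integer(0),
               stringsAsFactors = FALSE)
  blast <- if (length(blast) > 0) do.call(rbind, blast) else empty_blast()

  # planted variant sites
  if (!is.null(config$n_snps)) {
    n_sites_total <- as.integer(config$n_snps)
    alloc <- table(factor(sample(ids, n_sites_total, replace = TRUE,
                                 prob = lens), levels = ids))
  } else {
    alloc <- stats::rpois(n, lens * config$snp_density)
    names(alloc) <- ids
  }
  truth <- list()
  for (i in seq_len(n)) {
    k <- min(as.integer(alloc[[ids[[i]]]]), lens[[i]])
    if (k == 0L) next
    pos <- sort(sample.int(lens[[i]], k))
    ref <- strsplit(contigs[[i]]$sequence, "", fixed = TRUE)[[1]][pos]
    is_ti <- stats::runif(k) < config$titv_ratio / (config$titv_ratio + 1)
    alt <- character(k)
    alt[is_ti] <- transition_partner[ref[is_ti]]
    for (j in which(!is_ti)) {
      alt[[j]] <- sample(transversion_partners[[ref[[j]]]], 1L)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      contig_id = ids[[i]], position = pos, ref_allele = ref,
      alt_allele = alt,
      minor_frequency = draw_maf(config$minor_allele_frequency, k),
      planted_class = ifelse(is_ti, "transition", "transversion"),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(contig_id = character(0), position = integer(0),
               ref_allele = character(0), alt_allele = character(0),
               minor_frequency = numeric(0), planted_class = character(0),
               stringsAsFactors = FALSE)

  # planted codon position (from the primary ORF), survivability flag
  if (nrow(truth) > 0) {
    truth$planted_codon_position <- "none"
    for (r in seq_len(nrow(orfs))) {
      sel <- truth$contig_id == orfs$contig_id[[r]] &
        truth$position >= orfs$orf_start[[r]] &
        truth$position <= orfs$orf_end[[r]]
      if (!any(sel)) next
      qs <- if (orfs$frame_sign[[r]] > 0L) orfs$orf_start[[r]] else
        orfs$orf_end[[r]]
      qe <- if (orfs$frame_sign[[r]] > 0L) orfs$orf_end[[r]] else
        orfs$orf_start[[r]]
      truth$planted_codon_position[sel] <- as.character(
        codon_position_single(qs, qe, orfs$frame_sign[[r]],
                              truth$position[sel]))
    }
    lmap <- lens
    names(lmap) <- ids
    # representative read lengths: quantiles of the truncated normal model
    qlens <- pmax(config$read_len_min,
                  as.integer(round(stats::qnorm(seq(0.1, 0.9, by = 0.2),
                                                config$read_len_mean,
                                                config$read_len_sd))))
    surv <- logical(nrow(truth))
    for (j in seq_len(nrow(truth))) {
      cid <- truth$contig_id[[j]]
      len <- lmap[[cid]]
      pos <- truth$position[[j]]
      others <- truth$position[truth$contig_id == cid]
      others <- others[others != pos]
      surv[[j]] <- len > filters$min_contig_len &&
        (pos - 1L) >= filters$min_flank &&
        (len - pos) >= filters$min_flank &&
        (length(others) == 0L || min(abs(others - pos)) >= filters$min_gap) &&
        site_eligible_fraction(contigs[[cid]]$mask, pos, qlens,
                               filters$min_unmasked_run) >= 0.9
    }
    truth$ideal_survivable <- surv
  } else {
    truth$planted_codon_position <- character(0)
    truth$ideal_survivable <- logical(0)
  }
  rownames(truth) <- NULL
  list(contigs = contigs, truth = truth, blast = blast,
       isogroups = isogroups, orfs = orfs)
}

#' Simulate pre-aligned 454-like reads over a truth set
#'
#' Reads are sampled uniformly along each contig (start positions extend
#' past the contig ends and are clipped, so interior coverage is uniform at
#' the configured depth, as when reads span contig boundaries). At planted
#' sites each read draws the alternative allele independently with the
#' site's minor frequency. Substitution errors flip bases at the configured
#' rate; homopolymer runs of length >= 3 within a read gain or lose one
#' base at the configured per-run rate, encoded as I/D CIGAR operations at
#' the run's end. Reads inherit the repeat-mask case of the contig bases
#' they cover. Alignments are exact by construction — no mapper runs.
#'
#' @param contigs a `masked_contigs` collection from `generate_truth_set()`.
#' @param truth the matching truth data.frame.
#' @param config the `sim_config` used to generate the truth set; the read
#'   stream is seeded from `config$seed` (offset so it is independent of
#'   the truth stream).
#' @return alignment data.frame sorted by (contig_id, start, read_id),
#'   ready for `filter_eligible_reads()` / `build_pileup()` or `write_sam()`.
#' @export
simulate_reads <- function(contigs, truth, config = sim_config()) {
  stopifnot(inherits(contigs, "masked_contigs"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lens <- contig_lengths(contigs)
  L <- as.integer(config$read_len_mean)
  out <- list()
  for (cid in names(contigs)) {
    len <- lens[[cid]]
    refchars <- strsplit(contigs[[cid]]$sequence, "", fixed = TRUE)[[1]]
    cmask <- contigs[[cid]]$mask
    tsel <- truth[truth$contig_id == cid, , drop = FALSE]
    n_reads <- stats::rpois(1L, config$coverage * (len + L - 1L) / L)
    if (n_reads == 0L) next
    rl <- pmax(as.integer(config$read_len_min),
               as.integer(round(stats::rnorm(n_reads, config$read_len_mean,
                                             config$read_len_sd))))
    start0 <- as.integer(floor(stats::runif(n_reads) * (len + rl - 1L))) +
      2L - rl
    recs <- vector("list", n_reads)
    for (k in seq_len(n_reads)) {
      s <- max(1L, start0[[k]])
      e <- min(len, start0[[k]] + rl[[k]] - 1L)
      alen <- e - s + 1L
      bases <- refchars[s:e]
      # allele draws at planted sites covered by this read
      if (nrow(tsel) > 0) {
        cov <- which(tsel$position >= s & tsel$position <= e)
        for (j in cov) {
          if (stats::runif(1L) < tsel$minor_frequency[[j]]) {
            bases[[tsel$position[[j]] - s + 1L]] <- tsel$alt_allele[[j]]
          }
        }
      }
      # substitution errors
      if (config$substitution_error_rate > 0) {
        err <- which(stats::runif(alen) < config$substitution_error_rate)
        for (j in err) {
          bases[[j]] <- sample(setdiff(c("A", "C", "G", "T"), bases[[j]]), 1L)
        }
      }
      # homopolymer indels on reference runs of length >= 3
      opvec <- rep("M", alen)
      ins_after <- integer(alen)
      if (config$homopolymer_indel_rate > 0 && alen >= 4L) {
        runs <- rle(refchars[s:e])
        ends <- cumsum(runs$lengths)
        hp <- which(runs$lengths >= 3L)
        for (r in hp) {
          if (stats::runif(1L) >= config$homopolymer_indel_rate) next
          j <- ends[[r]]
          if (j < 2L || j > alen - 1L) next
          if (stats::runif(1L) < 0.5) {
            opvec[[j]] <- "D"         # run read one base short
          } else {
            ins_after[[j]] <- 1L      # run read one base long
          }
        }
      }
      read_case <- cmask[s:e]
      seq_parts <- character(0)
      ops <- character(0)
      oplens <- integer(0)
      push_op <- function(op, n) {
        if (length(ops) > 0 && ops[length(ops)] == op) {
          oplens[length(oplens)] <<- oplens[length(oplens)] + n
        } else {
          ops[length(ops) + 1L] <<- op
          oplens[length(oplens) + 1L] <<- n
        }
      }
      for (j in seq_len(alen)) {
        b <- bases[[j]]
        if (read_case[[j]]) b <- tolower(b)
        if (opvec[[j]] == "M") {
          push_op("M", 1L)
          seq_parts <- c(seq_parts, b)
        } else {
          push_op("D", 1L)
        }
        if (ins_after[[j]] > 0L) {
          push_op("I", ins_after[[j]])
          seq_parts <- c(seq_parts, rep(b, ins_after[[j]]))
        }
      }
      recs[[k]] <- data.frame(
        read_id = sprintf("%s_r%05d", cid, k), contig_id = cid, start = s,
        cigar = paste0(oplens, ops, collapse = ""),
        seq = paste(seq_parts, collapse = ""), stringsAsFactors = FALSE)
    }
    out[[cid]] <- do.call(rbind, recs)
  }
  if (length(out) == 0L) return(empty_alignments())
  aln <- do.call(rbind, out)
  aln <- aln[order(aln$contig_id, aln$start, aln$read_id), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Write a full simulated data set to disk
#'
#' Emits `contigs.fasta`, `reads.sam`, `blast.tsv`, `truth.tsv` and
#' `isogroups.tsv` under `outdir`.
#'
#' @param sim result of `generate_truth_set()`.
#' @param alignments result of `simulate_reads()`.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, alignments, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_masked_fasta(sim$contigs, file.path(outdir, "contigs.fasta"))
  write_sam(alignments, sim$contigs, file.path(outdir, "reads.sam"))
  write_blast_tabular(sim$blast, file.path(outdir, "blast.tsv"))
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_isogroup_map(sim$isogroups, file.path(outdir, "isogroups.tsv"))
  invisible(outdir)
}
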