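---
title: "Mining putative SNPs from a 454 transcriptome assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining putative SNPs from a 454 transcriptome assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmine)
```

## The problem

De novo transcriptome projects in species without a reference genome —
here the motivating case is a salmonid aquaculture species sequenced with
Roche 454 pyrosequencing — routinely mine their read-to-contig alignments
for putative single-nucleotide polymorphisms. The assembly pools several
outbred individuals, so genuine allelic variation is visible as columns of
the read pileup where two bases each draw solid support. The difficulty is
that 454 data and transcriptome assemblies generate abundant artifacts
that mimic such columns: homopolymer-run length errors that shift
alignments locally, repeat-derived mismapping, and paralogous sequence
variants (fixed differences between duplicated genes, expected at high
frequency in salmonids after their ancestral genome duplication).

`snpmine` implements the pileup-based detection and the conservative
filter cascade used for this setting, the transition/transversion and
codon-position annotation of accepted sites, the per-contig and
per-isogroup summary statistics, and a ground-truthed simulator that makes
the whole pipeline testable end to end without any external data.

## Detection model and filter cascade

Reads arrive pre-aligned (restricted SAM dialect: M/=/X, I, D, S). Each
reference-consuming aligned base increments the allele count of its column;
deletions and insertions consume coordinates without counting, and `N`
bases are ignored. A column with at least two distinct bases, each
supported by at least one read, is a candidate; the two best-supported
bases are its major/minor alleles (ties broken alphabetically, a fixed
rule so output is byte-deterministic).

The cascade then applies, in order:

| filter | rule | default | unit |
|---|---|---|---|
| read eligibility | read needs a run of consecutive unmasked bases | ≥ 100 | bp |
| contig length | contig must be strictly longer than | 100 | bp |
| depth | total component reads at the column | ≥ 5 | reads |
| minor allele | reads supporting the minor allele | ≥ 2 | reads |
| biallelic | third allele must stay below | 2 | reads |
| spacing | distance to any other surviving candidate | ≥ 50 | bp |
| flanks | contig sequence on each side | ≥ 25 | bp |

Three of these deserve comment.

**Read eligibility.** Reads are screened by their repeat-mask content
(soft-masked lowercase, or `N`): a read qualifies only if it carries at
least 100 consecutive unmasked bases. The rule is per read, not per base —
once a read qualifies, all of its aligned bases count. We read the
underlying mapping protocol as requiring at least 100 unmasked bases (the
conventional direction: repeat-dominated reads are the ones excluded), and
expose the threshold as `min_unmasked_run`.

**Spacing.** Homopolymer length errors produce clusters of spurious
disagreement columns within a read length of each other. The spacing rule
keeps only candidates at least 50 bp from any other surviving candidate.
Two open choices are made explicit and configurable: (i) both members of a
close pair are removed (`drop_both = TRUE`), the conservative reading
consistent with artifact suppression — a greedy keep-the-first variant is
available; (ii) spacing is evaluated among candidates that already passed
the evidence filters, not among raw candidates, so a low-depth artifact
cannot spoil a genuine neighbour. The cascade order is pinned by a test.

**Depth.** "Total component reads" is taken as the full column depth (all
four bases), not just the two allele counts; with the biallelic rule in
force the distinction is minor, but it is fixed and documented.

Every removed candidate records its first failing stage, and the audit
satisfies `candidates = accepted + Σ removals` exactly.

## Annotation

Transitions are A↔G and C↔T; everything else is a transversion.

Codon positions come from translated protein alignments (BLASTx tabular,
12 columns, optional explicit frame). The core coordinate assumption is
that a translated-alignment HSP begins in-frame: its starting query
coordinate is codon position 1 of its reading frame. On the forward frame
the anchor is the smaller query coordinate and `pos = ((snp − start) mod
3) + 1`; on the reverse frame the anchor is the larger coordinate and
positions count backwards. Alignment spans must be divisible by three;
records violating this are rejected with a warning. This assumption — and
the arithmetic — is checked against an independent translate-and-diff
oracle: substitute the allele, translate the constructed ORF (reverse
complement first on the reverse frame), and locate the changed codon base.

Evidence is consolidated per query under an all-alignments-agree rule:

* no covering alignment → `non_exonic` / `not_applicable`;
* all covering alignments agree → `exonic` with that position;
* covering alignments disagree → `exonic` / `uncertain`.

Coverage alone establishes exonic status (the uncertain class exists
precisely because exonic-but-ambiguous sites are reported separately), and
non-covering alignments neither support nor contradict.

## Summary statistics

`summarize_snps()` reports SNP-bearing contig and isogroup counts, means
and maxima per unit, single-SNP contigs, isogroups with two or more SNPs,
the Ti/Tv split, and density as bp per SNP. Contigs absent from the
isogroup map count as singleton groups. The density denominator is
supplied by the caller (total assembled bases by default in the workflow
scripts) because no single denominator is canonical; it is therefore
configurable rather than asserted. Display rounding is one decimal
(half-even, R's `round`), while the stored values keep full precision.

## The simulator: what it emulates, and what it does not

`generate_truth_set()` / `simulate_reads()` produce the study-shaped
inputs every test runs on. Defaults were chosen once, from the shape of a
normalized 454 transcriptome assembly, and are not tuned per test:

* **Contigs:** log-normal lengths, `meanlog = log(500)`, `sdlog = 0.6`
  (median ≈ 500 bp, matching an assembler's ~500 bp average contig with a
  long right tail); GC 0.45; repeat masking 10% of sequence in runs of
  mean 150 bp (short-interspersed-repeat scale).
* **Reads:** coverage 18× by default (the assembly scale this emulates
  averaged ~18×; validation runs use 25×), lengths normal(350, 100)
  truncated at 50 bp — ~350 bp is the Titanium-era aligned read length.
  Read starts extend past contig ends and are clipped, so interior
  coverage is uniform. Substitution errors at 10⁻³ per base; homopolymer
  runs of length ≥ 3 gain or lose one base with probability 0.01 per run,
  emitted as I/D CIGAR operations — the dominant 454 error mode the
  spacing filter targets.
* **Variants:** biallelic sites at one per 483 bp by default (or a fixed
  total `n_snps`), minor allele frequency 0.5 per read — the
  heterozygous-parent case of a pooled full-sib design; each read draws
  its allele independently, which ignores haplotype linkage across sites.
  Planted Ti:Tv is 2:1.
* **ORFs and alignments:** 45% of contigs carry an in-frame ORF with a
  translated-alignment record; half of the eligible ones get a second,
  consistent sub-alignment, and 5% instead get a frame-shifted conflicting
  duplicate, which must consolidate to `uncertain`.

Reads are emitted pre-aligned with exact coordinates — no mapper runs —
so expected pileups are known by construction. What the simulator does
*not* model: flowgram-level 454 noise and quality strings, transcript
abundance (the emulated library was normalized), chimeric reads,
alternative splicing within isogroups, and paralogous gene copies.
Passing tests therefore demonstrate the pipeline's correctness and its
behaviour under the modelled error modes, not immunity to PSVs or
mapping ambiguity in real data.

### Ideal-survivable sites

Sensitivity needs a denominator. A planted site counts as
*ideal-survivable* when an ideal cascade could accept it on grounds
deterministic from the truth alone: contig longer than 100 bp, both
flanks ≥ 25 bp, no planted neighbour within 50 bp, and expected
mask-eligible read coverage at least 90% of what an unmasked interior
site receives (integrated over read-length quantiles). The last clause
matters: a site deep inside a repeat run loses most of its covering reads
to the eligibility rule and cannot be expected to reach the depth
thresholds — by design, since repeat-internal variation is exactly what
the mask rule suppresses. Depth and minor-allele outcomes remain
read-dependent; at 25× coverage and minor frequency 0.5 the per-site
failure probability is the binomial tail
`P(minor ≤ 1 | d) ≈ (d + 1)·2⁻ᵈ ≈ 10⁻⁵`, negligible at validation scale.

## Numerical and degenerate-input choices

* All external coordinates are 1-based, fully closed (SAM/BLAST
  convention); no half-open representation leaks through an interface.
* Thresholds are inclusive exactly as phrased: depth 5 passes, minor 2
  passes, spacing at exactly 50 bp passes, a 25 bp flank passes, a 100 bp
  unmasked run qualifies a read, and a 100 bp contig does *not* (strictly
  longer required).
* Equal-count major/minor ties: alphabetical; verified by enumerating all
  two-allele configurations.
* Empty inputs yield empty, well-formed outputs (header-only SAM/TSV, a
  zero summary with the density reported absent, an all-zero audit).
* Zero-depth columns are omitted; `N` never forms an allele.
* The simulator clips infeasible event positions (no leading/trailing
  deletions in CIGARs) and clamps contig lengths at 50 bp.

## Validation scale

The checked properties run at fixed problem sizes chosen to make the
statistical assertions sharp but the suite quick: 1,000 random pileup
instances against a brute-force replay of the cascade rules, 1,000
planted ORFs (both frames) against the translate-and-diff oracle, and
end-to-end runs of 100 contigs / 500 planted sites at 25× coverage (a few
thousand reads), where the error-free configuration must recover every
ideal-survivable site with no false positives and the default-error
configuration must land the recovered Ti:Tv inside the 99% binomial
interval of the planted 2:1. The re-derivation of published summary
statistics from deposited supplementary SNP tables
(`rederive_published_summary()`) runs only when those tables are present
locally as TSV; they are too large to ship with the package.

## Known limitations

* No genotype-likelihood model: calls are threshold-based counts, as in
  the original pileup protocol; no base qualities are used.
* Indel variation is deliberately out of scope; deletions never form
  alleles.
* PSV/paralog discrimination is not attempted — a fraction of accepted
  "SNPs" in real salmonid data will be fixed paralog differences.
* One annotation namespace: alignments are joined to SNPs by contig id;
  cross-query merging (isotigs sharing contigs) is not performed.
* The per-read independent allele draw makes read evidence at linked
  sites independent, slightly optimistic relative to real haplotypes.
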