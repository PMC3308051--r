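---
title: "Variant discovery in an allotetraploid exon capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant discovery in an allotetraploid exon capture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycap)
library(data.table)
```

## The problem

An allotetraploid (AABB) genome carries two diverged diploid subgenomes. When
short reads from exon-capture libraries of such a species are aligned to a
single cDNA reference built from one representative homoeolog per gene, reads
from **both** subgenomes — and from any intra-genomic paralogs — pile up on the
same coordinates. A position showing two nucleotide variants within one
accession's reads (an *intra-species variable site*, IVS) can therefore mean
three different things:

* **GSS** (genome-specific site): a fixed difference between the A and B
  subgenomes, inherited from the diploid ancestors. Both accessions show both
  variants.
* **SNP**: a lineage mutation in one subgenome of one accession. That
  accession is an IVS; the other accession is monomorphic for one of the two
  variants. The shared variant is the ancestral state, the unshared variant
  the derived state, and the IVS-bearing accession is the derived lineage —
  ancestral/derived orientation falls out of the inter-genomic comparison
  with no outgroup.
* **Artifact**: paralogous copies aligned onto the target, creating spurious
  IVSs with skewed allele depth.

`polycap` implements this site taxonomy for exactly two accessions (a
cultivated-like `Ld` and a wild-like `Td` by default), together with the
coverage-based structural-variant detectors and coding-effect annotation that
complete the analysis, and a synthetic tetraploid generator that reproduces
the statistical structure the procedure assumes, with full ground truth.

## The classification filters

Variable sites (second pooled allele supported by ≥ 2 reads) pass through
three filters before labelling:

1. **Repetitive-target filter.** Targets whose median depth of coverage (MDC,
   computed over *all* bases, zero-coverage bases included) is at or above
   the 99th percentile of the MDC distribution of known single-copy targets
   are excluded wholesale; repetitive or multi-family targets attract reads
   from many loci. The percentile (`mdc_percentile`) and an explicit cutoff
   override are configurable; the filter inspects combined-accession MDC by
   default, with a `per_accession` switch, because the published procedure
   does not say which it used.
2. **Monomorphic-coverage filter.** A SNP call requires the non-IVS accession
   to be monomorphic at a depth of at least 8 reads (`min_mono_coverage`);
   shallower evidence cannot distinguish monomorphism from allele dropout.
3. **Depth-ratio filter.** For every IVS the log2 ratio of reads matching the
   reference base to reads carrying the alternative is compared to
   per-accession windows (defaults +1.6/−1.6 for the first accession,
   +1.0/−1.0 for the second). Single-copy targets cluster near a
   characteristic ratio set by capture bias; paralog contamination pushes the
   ratio up (three reference-like copies against one alternative give 3:1).
   Only upper thresholds are published; the lower threshold defaults to the
   negated upper.

Sites with a third allele above a one-read error tolerance are filtered as
triallelic rather than decomposed — the taxonomy is biallelic. Sites where
*both* accessions are fixed, for different alleles, cannot be classified as
GSS or SNP; they are filtered with reason `no_ivs` (this is precisely the
homoeolog-deletion signature that the structural detector consumes — the
reason label is a small extension of the published filter vocabulary).

### Threshold calibration

`calibrate_ratio_thresholds()` reproduces the published calibration: given
log2 ratios of validated true and false IVSs, it returns the largest
threshold *u*, scanned over the merged observed values, such that among sites
with ratio ≤ *u* the fraction drawn from the false set stays at or below the
target rate (5% by default). The scan takes the largest empirically feasible
candidate; on draws of a few hundred sites that choice sits exactly on the
target boundary, so an independent draw fluctuates around the target — with
tens of thousands of calibration sites the rule concentrates just below it.
`simulate_ivs_ratios()` generates matched synthetic mixtures: true IVSs as
binomial 1:1 allele splits at Poisson depth (λ = 13) with a mild reference
bias of 0.55 (capture favours the bait-matching variant), false IVSs as
binomial 3:1 splits.

### Flank rescue

A SNP call can be a disguised GSS whose second variant never aligned: if the
diverged subgenome's reads around the site exceed the aligner's mismatch
budget, the monomorphic accession looks clean. `flank_rescue()` builds a
40-bp query of reference context centred on the site (shrunk at target
boundaries, with a warning), substitutes the candidate missing variant at the
centre, and scans the monomorphic accession's raw reads on both strands for a
match with ≤ 3 mismatches that covers the site and carries the variant.
Queries are centred rather than one-sided: with 40-bp reads a centred window
maximises the achievable read/query overlap (minimum overlap 20 bp). Rescued
calls are re-labelled `filtered/flank_rescued`.

### The theoretical error term

Under Poisson coverage with mean λ and equal sampling of two variants, the
probability that only one variant of a divergent site is ever sequenced is
`2·exp(−λ)`. Multiplying by the expected number of divergent sites `d·L`
gives `expected_missed_variant_sites()`. At λ = 13, d = 0.02 and L = 3.5 Mb
this is ≈ 0.3 sites — chance dropout is negligible, so observed false SNP
calls must come from capture bias and paralogy, which is what motivates the
ratio filter and flank rescue. The per-site probability is capped at 1 so
the formula stays a count for tiny λ. (The published formula writes an
additional factor of 2 that is already contained in `p = 2·exp(−λ)`; the
implementation multiplies `p` by `d·L` directly, which reproduces the
printed value.)

## Structural variation

Two complementary detectors:

* **Windowed coverage ratio** (`window_counts()`, `window_ratio_test()`,
  `call_cnv()`): targets with ≥ 70% breadth are tiled into 500-bp windows at
  250-bp step; each window's library-normalised count ratio is tested with
  the normal approximation to a log ratio of Poisson counts,
  `z = ln(r)·(1/x + 1/y)^(−1/2)`, two-sided, with a 0.5 continuity
  correction for empty cells. A target is a CNV when at least four windows
  are significant at α = 0.001 **and** agree in sign — a copy-number change
  cannot be simultaneously gain and loss. The exact Geary–Hinkley
  transformation used by CNV-seq-style tools is replaced by this log-ratio
  approximation because it is self-contained and asymptotically equivalent;
  α is exposed because the published significance level is not stated.
  Mechanism: a CNV target with *no* variable sites is a deletion in the
  lower-coverage accession; a variable-site count above the non-CNV baseline
  indicates multigene-family copy change in the higher-coverage accession
  (duplication margins under 10% over baseline are flagged low-confidence).
* **Variant-pattern detectors**: whole-gene PAV requires MDC 0 in one
  accession and ≥ 10 in the other; `homoeolog_deletion()` calls a subgenome
  loss when more than 70% (strict) of a target's variable sites show one
  accession with a single variant where the other shows two, over at least 3
  variable sites (a floor that keeps the fraction meaningful; one-site genes
  would trigger trivially). When both accessions are fixed for consistently
  different alleles the call is a reciprocal deletion. PAV targets are
  excluded from the windowed detector — the dedicated call wins, and a
  zero-coverage side would otherwise produce degenerate window statistics.

## Read preparation

Reads carry accession tags; demultiplexing requires phred ≥ 15 over the
first four bases, assigns by longest matching tag prefix (an empty tag
declares a no-tag class), and trims the tag. The aligner re-implements the
relevant semantics of bowtie's `-m1 -n2`: ungapped end-to-end placement, at
most 2 mismatches in the first 28 bases, a total mismatch cap of 3
(approximating the quality-sum ceiling), both strands searched, and any read
with more than one valid placement suppressed. Candidate placements come
from pigeonhole seed chunks hashed over the reference (with ≤ 2 seed
mismatches, one of three disjoint 9-mers must match exactly), implemented in
C++; tiny references fall back to a full scan.

Unaligned reads are rescued by iterative trimming: at each trimmed length
every split of the trim between the 3' and 5' ends is tried, 3'-heavy
candidates first (the published procedure trims "3' or 5'" without stating
an order; 3' priority follows the quality-decay convention and keeps both
ends reachable), recursing until alignment or a 30-bp floor. Finally,
mismatches within 3 bases of an alignment end are distrusted and trimmed
through (`trim_edge_mismatches()`): junction reads can align while carrying
a short intronic residue inside the mismatch budget, and because every read
over the same junction carries the same residue, those mismatches otherwise
pile into clustered artifact variant columns.

## Coding effects

Gene models partition each cDNA into 5' UTR, CDS and 3' UTR with the frame
anchored at the CDS start. Effects are classified by translating the codon
with the ancestral and derived alleles substituted (standard nuclear code;
the targets are nuclear cDNAs): synonymous, non-synonymous, stop gain, stop
loss; stop-to-stop changes are synonymous because the protein is unchanged;
UTR sites are `utr`. GSSs are oriented from the reference-matching allele in
the reference homoeolog's frame. GO enrichment cross-tabulates replacement
(non-synonymous plus stop gain/loss) versus synonymous changes in-group
versus out-group per GO term, tests two-sided with Fisher's exact test, and
controls FDR by Benjamini–Hochberg step-up — the conventional reading of an
"FDR < 0.05" correction of that era.

## The synthetic tetraploid generator

`sim_config()` defaults describe the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | cDNA targets (desk-scale stand-in for thousands) |
| `gene_length_range` | 800–1200 bp | cDNA length (≈ 1 kb targets) |
| `utr5/cds/utr3_frac` | 0.04/0.65/0.31 | targeted sequence composition |
| `divergence_d` | 0.02 | A/B coding divergence per bp |
| `utr_divergence` | = d | UTR divergence (not published separately) |
| `snp_rate_cds/utr5/utr3` | 1.3/2.0/1.6 per kb | lineage SNP densities |
| `mean_depth_lambda` | 13 | per-accession depth of an unbiased gene |
| `read_length` | 40 | single-end read length |
| `seq_error_rate` | 0.002 | per-base substitution error |
| `n_paralog_genes` | 10 | genes with a 5%-diverged paralog in both accessions |
| `n_homoeolog_deletions` | 4 | subgenome losses (last one partial when ≥ 2) |
| `n_pav_genes` | 3 | whole-gene absences |
| `n_duplicated_families` | 5 | genes with 2 extra copies in one accession |

Event counts are a handful per 200 genes — enough to exercise every
detector while keeping events rare, as they are in real accessions. Each
gene gets an ancestral cDNA whose ORF starts with ATG, ends with a stop and
contains no internal stops (rejection-free by construction from sense
codons), plus 1–3 introns of 60–200 bp. The B homoeolog is mutated from the
ancestral sequence at rate *d* (these positions **are** the GSS truth);
accessions add lineage SNPs at the regional rates on one subgenome copy
each, disjoint from GSS positions and from each other by default so that
every planted event has an unambiguous expected call. All mutations are
single-base substitutions — indel discovery is out of scope. The reference
takes one homoeolog per gene, alternating A/B by index, which is
deterministic and balanced.

Reads are drawn from the intron-containing genomic copies (so a realistic
fraction straddles junctions), on both strands, with Poisson counts per copy
scaled by `capture_efficiency(divergence) = 0.5^(divergence/0.02)` — the
two-fold coverage loss per 2% divergence from the bait. A copy's expected
depth is `λ/2 × efficiency`, so an unbiased single-copy gene totals λ per
accession. Qualities are constant phred 35 with errors injected into the
sequence; quality modelling is not the subject here.

**What the generator does not emulate:** GC- and thermodynamics-driven
capture variability, indels, adapter chemistry, quality decay along reads,
between-copy gene conversion, and population-level allele frequencies
(each accession is a single homozygous line). Passing recovery tests on this
generator therefore demonstrates the correctness of the discovery logic
under the stated statistical model, not performance on any particular real
library.

## Numerical choices and degenerate inputs

* Percentiles use R's default type-7 linear interpolation.
* `window_ratio_test()` substitutes 0.5 for zero counts (both in the ratio
  and its variance); windows empty in both accessions are skipped.
* Targets shorter than one 500-bp window are tested as a single full-length
  window and the four-window requirement scales down to the number of
  windows available.
* Ties between trim candidates at the same length resolve 3'-first; ties
  between pooled allele counts resolve in base order (A < C < G < T).
* k-mer windows containing non-ACGT bases are skipped (a 2-bit alphabet has
  no ambiguity codes); k ≤ 32 so a k-mer fits one 64-bit word.
* One seed governs a whole run; the read simulator derives its stream from
  the same seed so reference and read generation are independently
  reproducible, and identical configurations produce byte-identical files.

## Problem sizes

The bundled tests run the generator at 1–200 genes. The full end-to-end
configuration (200 genes, λ = 13, ≈ 90k reads) classifies several thousand
variable sites in about a minute on one core; threshold-calibration
experiments use 20,000 true and 5,000 false IVSs per draw, a size at which
the calibrated threshold's out-of-sample false-IVS rate concentrates within
half a percentage point of the 5% target.

## Known limitations

* Exactly two accessions; multi-accession designs would need a generalised
  site taxonomy.
* The aligner is ungapped by design; reads spanning indels are unalignable
  rather than gapped-aligned.
* Homoeolog-deletion evidence is depth-pattern only; breakpoints are not
  resolved.
* GO terms are consumed from a user-supplied table, never produced.
* The SNP validation literature this procedure derives from reports one
  internally inconsistent count (a 30% rate printed as "14 of 43" where the
  set arithmetic gives 13); `validation_confusion()` reports raw counts and
  computed rates and takes no side.
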