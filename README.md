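# polycap

Variant discovery from exon capture in allopolyploid genomes.

## The problem

In an allotetraploid (AABB) species, every gene exists as two diverged
homoeologous copies inherited from distinct diploid ancestors. Short reads
from an exon-capture experiment aligned against a single cDNA reference mix
reads from both subgenomes — and from intra-genomic paralogs — on the same
coordinates, so a naive variant caller cannot tell a fixed inter-genomic
difference from a real mutation. `polycap` is for researchers analysing
capture re-sequencing of polyploids (two accessions at a time) who need to
separate three things that look identical in a pileup:

* **GSS** (genome-specific sites): fixed A/B subgenome divergence — both
  accessions show both variants;
* **SNPs**: lineage mutations — one accession shows both variants (the
  derived lineage), the other is monomorphic for the ancestral one, which
  orients every SNP without an outgroup;
* **paralog artifacts**: spurious variable sites whose allele depth ratio
  deviates from the single-copy expectation.

The classifier combines a repetitive-target filter (99th percentile of
single-copy median depth), an 8-read monomorphic-coverage floor, a
calibrated log2 allele-depth-ratio window (`log2(ref/alt)` thresholds
1.6/1.0 by default, calibrated to hold the false-IVS rate at 5%), and a
flank-rescue scan that unmasks hidden divergence by searching raw unaligned
reads for the missing second variant. Around it sit the full pipeline
stages: tag demultiplexing, a bowtie-like unique-alignment mini-aligner with
iterative trim rescue of exon-junction reads, per-base pileups and coverage
summaries (MDC, breadth, expected depth `total aligned bases / target
length`, fold enrichment), windowed coverage-ratio CNV detection
(`z = ln(r)·(1/x+1/y)^{-1/2}`, ≥ 4 significant 500/250-bp windows of
consistent sign), presence/absence calls (MDC 0 vs ≥ 10), homoeolog-deletion
detection (> 70% single-variant sites), coding-effect annotation with GO
enrichment (Fisher exact + Benjamini–Hochberg), and assay QC (GC screen,
32-mer abundance index). A deterministic synthetic tetraploid simulator with
full ground truth drives the tests; the key theory term
`T = 2·exp(−λ)·d·L` quantifies how unlikely pure chance dropout of a second
variant is (≈ 0.3 sites at λ = 13 over 3.5 Mb at 2% divergence).

## Worked example

Simulate a 40-gene capture experiment for two accessions (`Ld`, `Td`) with
planted paralogs, a PAV gene, homoeolog deletions and a duplicated family,
then run the whole pipeline:

```r
library(polycap)
cfg <- sim_config(n_genes = 40, seed = 11, n_paralog_genes = 2,
                  n_homoeolog_deletions = 2, n_pav_genes = 1,
                  n_duplicated_families = 1, mean_depth_lambda = 20)
run <- run_pipeline(cfg)
print(run)
#> polycap pipeline run
#>   reads: 29820 total, 29820 assigned, 26252 aligned (2539 rescued, 0 multi-hit)
#>   coverage: median MDC 27.0, MDC cutoff 30.0 (4 targets excluded)
#>   site calls: filtered 730, GSS 150, SNP 58
#>   structural: 1 CNV, 1 PAV, 1 homoeolog deletions
#>   GSS: FPR 0.013 FNR 0.819 | SNP: FPR 0.121 FNR 0.598
```

Reading this: 29,820 tagged 40-bp reads were demultiplexed and aligned with
unique-alignment semantics; 2,539 junction reads only aligned after
iterative end-trimming. Four targets exceeded the single-copy MDC cutoff
(30×) and were excluded as repeat/paralog attractors. Of the variable sites,
150 classified as fixed inter-genomic divergence (GSS) and 58 as lineage
SNPs; the rest were filtered with a recorded reason (ratio out of range, low
monomorphic coverage, triallelic, flank-rescued, ...). Against the planted
truth, GSS false positives are rare (1.3%) while the false-negative rate is
high (82%) — the expected signature of capture bias against the diverged
subgenome combined with conservative ratio thresholds, not a defect. The
structural detectors recovered the planted PAV gene and a full homoeolog
deletion:

```r
run$homoeolog_deletions
#>      target               kind accession n_sites single_variant_fraction
#> 1: gene0014 homoeolog_deletion        Ld      16                  0.9375
```

The two closed-form quantities most often quoted from this kind of assay:

```r
expected_missed_variant_sites(13, 0.02, 3.5e6)  # 0.316 -> ~0.3 sites
expected_mdc(383e6, 3.5e6)                       # 109.4 reads per base
```

A thin CLI wraps the same functions
(`inst/scripts/polycap simulate|align|classify|cnv|annotate|kmer-index|run`).

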