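# twinmeth

Differential DNA methylation analysis for reduced representation bisulfite
sequencing (RRBS) of paired sample designs — in particular monozygotic (MZ)
twin pairs discordant for a condition such as trisomy 21 (T21), where the
shared genome removes inter-individual genetic background from the
case/control comparison.

## What it does

The package implements the promoter-centric DMR pipeline used in twin RRBS
studies, end to end:

* **Methylation calling.** Per-CpG percent methylation from Bismark-style
  cytosine count reports, `percent = 100·m/(m+u)`, keeping CpGs covered by
  at least 20 reads (base quality is assumed filtered upstream at
  Phred ≥ 20). Bisulfite conversion is estimated from non-CpG cytosines and
  technical-replicate concordance as the Pearson correlation over shared
  CpGs.
* **Region scoring.** Promoters (−2000 bp, +1000 bp around the TSS,
  strand-aware), CpG islands and their 2 kb shores, exons, introns, LADs
  and iLADs. A region's methylation is the percentage of methylated
  cytosines over all covered cytosines in the region — a count-pooled
  (coverage-weighted) density — and requires at least three CpGs each
  covered by 20 reads.
* **Promoter DMR testing.** For each promoter, a two-sided Fisher's exact
  test on the pooled 2×2 table of methylated/unmethylated counts
  (case vs control), p-values converted to q-values with a sliding linear
  model (SLIM) estimate of the null proportion π₀ (Benjamini–Hochberg
  available as cross-check), and a DMR call when `q ≤ 0.001` and
  `|Δmethylation| ≥ 25` percentage points, signed case − control.
* **Filtering cascade.** DMRs of the discordant twin pair, minus anything
  also called in control twin pairs (normal MZ twins, condition-concordant
  twins), intersected with the unrelated case/control comparison — the set
  algebra that isolates condition-induced candidates, with hyper/hypo
  tallies at each stage.
* **Global comparisons.** Feature-level Mann–Whitney U tests (exact for
  small samples, tie-corrected normal approximation otherwise), per-CpG
  difference histograms in both orientations, and a strand-aware metagene
  profile (−10 kb..+1 kb of the TSS in 44 × 250 bp bins, a 60-bin scaled
  gene body, −1 kb..+10 kb of the TTS, and intergenic) with per-bin
  methylation-density fold changes.
* **Expression integration.** Quantile normalisation of RPKM tables, log2
  fold changes of replicate group means, Pearson correlation of
  Δmethylation vs expression change, and generic hypergeometric gene-set
  enrichment over user-supplied GMT files.
* **Synthetic data.** A beta-binomial RRBS simulator (negative-binomial
  coverage, per-class beta baselines, planted promoter DMRs, a global
  hypermethylation shift, technical replicates, residual non-CpG
  methylation) with a ground-truth ledger, so the whole pipeline is
  testable without external data. Two published reference DMR tables are
  packaged as fixtures.

## Worked example

Simulate a discordant twin pair with 20 planted promoter DMRs at ±40
percentage points, call DMRs, and run the cascade against a control twin
pair and an unrelated pair:

```r
library(twinmeth)

planted <- data.frame(region_class = "promoter",
                      delta_percent = rep(c(40, -40), c(15, 5)))
cfg <- simulation_config(seed = 7, n_promoters = 200,
                         chromosome_length = 5e6, n_chromosomes = 2,
                         planted_dmrs = planted)
disc <- simulate_methylomes(cfg)
cs_disc <- dmr_comparison(disc, "discordantT21")
cs_disc
#> comparison_set 'discordantT21': T21_rep1+T21_rep2 vs Normal_rep1+Normal_rep2; 20/200 DMRs

ann <- disc$annotation
ctrl <- dmr_comparison(simulate_methylomes(simulation_config(
  seed = 8, n_promoters = 200, chromosome_length = 5e6,
  n_chromosomes = 2, n_replicates = 1L,
  groups = c(case = "twinA", control = "twinB")), ann), "normalTwins")
unrel <- dmr_comparison(simulate_methylomes(simulation_config(
  seed = 9, n_promoters = 200, chromosome_length = 5e6,
  n_chromosomes = 2, n_replicates = 1L, planted_dmrs = planted,
  groups = c(case = "unrelT21", control = "unrelN")), ann), "unrelated")

run_cascade(cs_disc, list(ctrl), unrel)
#> DMR filtering cascade:
#>   initial            20  (15 hyper / 5 hypo)
#>   after_exclusion    20  (15 hyper / 5 hypo)
#>   final              20  (15 hyper / 5 hypo)
```

All twenty planted DMRs are recovered, none are lost to the control
exclusion, and the hyper/hypo split matches the planted signs.

The packaged reference table of final T21 promoter DMRs behaves the same
way as in the published analysis it transcribes:

```r
t21 <- dmr_reference_table("t21")
nrow(unique(t21[c("chrom", "start", "end")]))   # 35 promoter intervals
length(unique(t21$gene))                        # 37 genes
direction_discordance(dmr_reference_table("chd"))
#> [1] "CBFA2T3"  "EPHA8"    "LY9"      "SLC9A3R2"
```

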