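---
title: "Statistical methods behind twinmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind twinmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

twinmeth analyses reduced representation bisulfite sequencing (RRBS) data
from paired designs, built around the comparison of monozygotic twins
discordant for a condition. This vignette explains the statistical model
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## Methylation calling

A cytosine report row carries methylated (`m`) and unmethylated (`u`)
read counts for one cytosine. The methylation call is
`percent = 100·m/(m+u)`, computed only for CpG-context rows with coverage
`m + u ≥ 20` (the `min_coverage` default). Base-call quality filtering
(Phred ≥ 20) belongs to read processing, upstream of the count file; the
reader records this assumption instead of re-implementing base-quality
logic, so counts are taken at face value.

Two quality metrics accompany calling. The **bisulfite conversion rate**
exploits the near-absence of non-CpG methylation in differentiated human
cells: non-CpG cytosines are presumed unmethylated, so
`100·Σu/Σ(m+u)` over CHG/CHH rows estimates the fraction of cytosines the
chemistry converted. No coverage filter applies here — every non-CpG read
is evidence. **Technical-replicate concordance** is the Pearson
correlation of percent values over CpGs called in both replicates; for
RRBS libraries prepared independently from one culture values near 0.9
are typical, and the simulator is parameterised to reproduce that regime
(below).

CpG dyads can be merged across strands (`destrand()`): the minus-strand
cytosine at position *p* belongs to the same dyad as the plus-strand
cytosine at *p − 1*, so counts are summed and reported at the plus
position. The default leaves strands separate, matching the per-strand
accounting of the upstream toolchain; both behaviours are exposed because
conventions differ between pipelines.

## Regions and their methylation

Coordinates are 0-based half-open internally (BED convention); cytosine
reports remain 1-based at the file boundary. This split is deliberate —
converting once, at input, avoids off-by-one ambiguity in interval
arithmetic.

The annotation model derives:

* **promoters**: `(−2000, +1000)` around the TSS, oriented by strand (for
  a minus-strand gene the TSS is `txEnd` and the offsets mirror), giving
  3000 bp windows. Promoters with identical coordinates — bidirectional
  gene pairs — collapse to a single interval listing every gene symbol,
  so region-level statistics are not double-counted while reports can
  still expand to genes.
* **CpG shores**: 2000 bp on each side of an island, with island overlap
  subtracted.
* **introns**: gene span minus exons, when only exons are supplied.
* **iLADs**: complement of the LADs within chromosome bounds.

Region methylation is **count-pooled**: `100·Σm/Σ(m+u)` over the passing
CpGs inside the interval — the percentage of methylated cytosines among
all covered cytosines, equivalently the coverage-weighted mean of per-CpG
percents (an algebraic identity the tests verify to 1e-9). An unweighted
mean of CpG percents would weight a 20X and a 200X site equally; the
density definition does not. A region needs at least three passing CpGs
(`min_cpgs = 3`) to be scored at all; below that it is *missing*, never
zero, and missing regions are skipped rather than imputed downstream.

## Promoter DMR testing

For each promoter scored in both groups (replicate counts summed within
group first), the 2×2 table

|          | methylated C | unmethylated C |
|----------|--------------|----------------|
| case     | m₁           | u₁             |
| control  | m₂           | u₂             |

is tested with a two-sided Fisher's exact test: the p-value sums the
hypergeometric probabilities of every table with the observed margins
whose probability does not exceed the observed table's. Two-sided Fisher
conventions differ exactly here, so the rule is stated and a relative
slack of 1e-7 absorbs floating-point ties. The implementation is checked
against full enumeration from binomial coefficients for every table with
margins up to 30.

Multiple testing uses a sliding-linear-model (SLIM) q-value: the
empirical CDF of the p-values is evaluated on the grid
λ = 0.01, 0.06, …, 0.96 and straight lines are fitted to sliding windows
of five grid points. On the null-dominated upper range of the CDF the
slope estimates the null proportion π₀; signal concentrates near zero and
inflates early-window slopes, so slopes are clamped at 1 and π₀ is the
median over windows starting at λ ≥ 0.25, floored at 0.05. The q-value is
then `π₀ · p · n / rank`, monotonised from the largest p down — π₀ times
the Benjamini–Hochberg adjustment, which is also available directly
(`q_method = "bh"`) as the cross-check: under a uniform null the two must
agree within the π₀ estimate, and the tests require π₀ ∈ [0.8, 1] there.

A promoter is a DMR when `q ≤ 0.001` **and** the methylation difference
(case − control, in percentage points) is at least 25 in absolute value.
The effect-size threshold matters as much as the q-value: pooled counts
run to thousands of cytosines per promoter, so trivially small
differences reach extreme significance, and in simulations it is the
25-point rule — not the q threshold — that keeps the false-positive count
near zero when technical noise makes counts slightly overdispersed
relative to the binomial.

### The filtering cascade

Condition-induced candidates are isolated by set algebra over comparisons
sharing one promoter universe: start from the discordant pair's DMRs,
remove anything also called in a control comparison (normal twin pairs or
condition-concordant pairs — twin-specific epigenetic variation), and
keep only what replicates in an unrelated case/control comparison. Region
identity is the exact promoter key (the gene-anchored 3 kb window), since
every comparison is tested over the same promoter set; overlap-based
matching is unnecessary and not implemented. Individual promoters may be
missing from one comparison for lack of coverage, so the sanity check on
inputs rejects *disjoint* key spaces (a different annotation) rather than
demanding exact equality. Hyper/hypo tallies at each stage use the sign
of the discordant comparison's difference.

## Global comparisons

Feature-level shifts are tested with a two-sided Mann–Whitney U test on
the paired per-region percent vectors — used, as is conventional for
global methylome comparisons, as a distribution-shift test. The p-value
is exact (from the null U distribution) when both samples have at most 50
values and no ties; otherwise a normal approximation with tie correction
and continuity correction is used. The exact path is verified against
complete enumeration of all group assignments for sizes up to 8.

The per-CpG difference histogram is computed in both orientations
(case − control and its negation). Differences are assigned to the
*nearest* bin center (centers at multiples of the bin width), a rule
symmetric under negation, so the two orientations are exact mirror
images; any edge-based binning breaks that invariant whenever a
difference lands exactly on a break — which happens constantly, since
identical percents give exactly zero.

### Metagene profile

Genes are aligned at TSS and TTS, strand-aware (bin 1 is always
biological upstream): a promoter flank from −10 kb to +1 kb of the TSS, a
gene body from +1 kb after the TSS to −1 kb before the TTS, a TTS flank
from −1 kb to +10 kb, and a pooled intergenic remainder. The flanks use
44 fixed 250 bp bins and the body 60 proportionally scaled bins — enough
to resolve the TSS peak while keeping on the order of ten or more CpGs
per bin in the packaged simulations; genes shorter than 2 kb have no body
and are excluded with a warning. Counts are pooled across genes per bin
and the per-bin density is `100·Σm/Σ(m+u)`; the profile reports the
case/control density ratio. Fold change is only defined where both
densities are positive — zero-density bins are flagged, with no
pseudocount by default. Pooling densities (rather than averaging
per-gene fold changes) follows directly from the density definition of
region methylation.

## Expression integration

Quantile normalisation replaces each column's sorted values by the
across-column rank means, ties receiving the mean of the reference values
over their rank range; it makes column distributions identical and is
idempotent. Group fold changes are `log2(mean case / mean control)` over
replicate columns, with zero means flagged rather than infinite (a
pseudocount is available but off by default, since the choice is
substantive and better made explicitly). Methylation–expression coupling
is summarised by the plain Pearson correlation between per-gene
methylation differences and expression log2 fold changes; promoter
hypermethylation that represses transcription appears as negative r.

The packaged reference table of morphogenesis genes illustrates a caveat
worth stating: recomputing Pearson's r from its fibroblast columns gives
+0.11, not a strong negative value — a single gene with a large positive
methylation difference *and* positive expression change dominates seven
points. The iPSC columns recompute to −0.56. The package always reports
the recomputed value.

Gene-set enrichment is a generic upper-tail hypergeometric test against
user-supplied sets (GMT), BH-adjusted across sets. The default universe
is the set of genes with a scored promoter, not the whole genome —
promoter coverage is what made a gene testable, and enrichment against
untestable genes would be biased. Database-backed GO or regulatory
enrichments are deliberately out of scope: their p-values depend on
database versions and are not reproducible offline.

## The synthetic-data generator

The simulator emulates the statistical structure the analysis assumes,
not the sequencing process:

* **Coverage** is negative-binomial with mean 30 and dispersion φ = 0.1
  (`variance = μ + φμ²`) — RRBS coverage is overdispersed; φ = 0 gives
  Poisson as a degenerate setting.
* **Methylation** is beta-binomial: each CpG draws a latent level from a
  beta distribution by region class — islands low (Beta(1,9), mean 10%),
  promoter non-island CpGs intermediate (Beta(3,7)), background high
  (Beta(7,3)) — reproducing the bimodality of real methylomes. The study
  does not report per-feature baselines, so these are conventional
  choices, not fitted values.
* **Twins share their baseline**: both groups use the same latent levels,
  as genetically identical twins share their epigenetic starting point;
  the case group adds the configured global shift (promoter/island CpGs)
  and the planted DMR deltas, all on the percent scale, clamped to
  [0.01, 0.99]. Planted promoters re-draw their baselines uniformly in
  the range that keeps baseline + delta inside [0.05, 0.95], so the
  realised difference equals the planted one in expectation.
* **Replicates** share the group-level methylation and re-draw counts
  with independent per-CpG jitter (`replicate_noise_sd`, percentage
  points). The default of 4 was chosen so replicate correlations land
  around 0.90 — the regime reported for independent library preparations
  from one culture — measured as 0.904/0.898/0.886 at jitter 3/4/5.
* **Non-CpG cytosines** are emitted at 0.2% true methylation, so
  conversion-rate estimation returns ≈ 99.8%.
* **Expression** couples to the truth ledger:
  `log2FC = −slope · Δ/100 + noise` (default slope 3, noise sd 0.5),
  with log-normal baselines and small replicate noise.
* **Determinism**: every sample draws from its own RNG stream derived
  from the master seed, so outputs are byte-identical under a fixed seed
  and adding samples never perturbs earlier ones. Planted DMRs go to
  evenly spaced promoters, deterministically, so independently simulated
  comparisons over one annotation plant them at identical intervals —
  which is what makes the cascade testable.

What the generator does **not** emulate: reads (no FASTQ, no MspI
fragment model beyond CpG clustering in promoters), mapping artefacts,
strand asymmetries (all CpGs are emitted on the plus strand),
batch effects, or biological between-twin variation beyond the planted
signal. Passing tests therefore demonstrate that the pipeline recovers
the signals it models, under the noise it models — not that real libraries
meet these assumptions.

## Problem sizes and numerical behaviour

The packaged end-to-end checks run at a deliberate scale: 2000 promoters
of 20 CpGs at 30X with two replicates per twin for DMR recovery (100
planted DMRs at ±40 points; sensitivity is required ≥ 0.9 with at most
one false call among 1900 nulls, and the cascade must return exactly the
planted set), and the same genome with a +5-point global shift for the
Mann–Whitney and metagene checks. At these sizes the per-bin metagene
fold change has a standard deviation of roughly 0.8–1.1% (binomial
counting error at 15–30 thousand pooled reads per bin, widest in the
low-density island bins), so the zero-shift requirement that every bin's
fold change stay within [0.97, 1.03] operates at about three standard
deviations — tight enough to catch systematic bias, loose enough to hold
under counting noise.

Other numerical choices: degenerate Fisher tables (a zero margin) return
p = 1 with a flag rather than an error; Mann–Whitney with all values tied
returns p = 1; correlation of a constant vector is an error, not NaN;
duplicate cytosine records are an input error, never silently summed; and
the packaged reference tables are checksum-verified on load.

## Limitations

* Promoter-level testing only — no tiling-window or single-CpG DMR
  calling.
* The pooled Fisher test assumes binomial counts within groups;
  replicate-aware overdispersion models (beta-binomial regression) are
  out of scope, and the 25-point effect threshold is what protects the
  false-positive rate when that assumption bends.
* SLIM's π₀ estimate follows the sliding-linear-model idea with the
  defaults stated above; other segmentations of the CDF give slightly
  different π₀. Under the null the result stays within 25% of BH, which
  is the calibration the tests enforce.
* Counts at the scale of a full human RRBS experiment (millions of CpGs,
  hundreds of DMRs across comparisons) are not reproduced; the packaged
  simulations are sized for minutes of compute, and the reference tables
  stand in for the published end points.
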