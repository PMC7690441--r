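---
title: "Methods: pooled homozygosity mapping and expression screens"
author: "screenmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled homozygosity mapping and expression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmap)
```

## The problem

Forward genetic screens in zebrafish induce point mutations with ENU and
recover recessive phenotypes in F2 incrosses. Identifying the causal lesion
by whole-exome sequencing of phenotype-sorted pools (bulked segregant
analysis, BSA) replaces positional cloning: the mutant pool is homozygous
for the mutagenized founder haplotype around the lesion, while elsewhere in
the genome both pools segregate the same background variation. screenmap
implements this mapping computation and the companion expression analyses
of such a screen — FPKM quantification with pure fold-change differential
calls, a splice-junction usage screen, and ddCt qPCR quantification —
together with seeded simulators that make every stage testable without any
external data.

## Homozygosity mapping

### Pool zygosity calls

Each variant site carries allelic depths for the wild-type-sibling pool and
the mutant pool. A pool is called homozygous-alternate when its alternate
fraction is at least `homAltMinFrac` (default 0.9), homozygous-reference
below the complementary bound, `nocall` under `minDepth` (default 10), and
heterozygous otherwise. A site is *mutant-specific homozygous* when the
mutant pool is hom-alt and the sibling pool is not: siblings of a recessive
mutant are expected to segregate the allele (2 het : 1 hom-ref), so a
heterozygous sibling pool is compatible with mutant specificity, and only a
hom-alt sibling pool (or a nocall) vetoes it. The thresholds apply to
*pooled* reads, not individual genotypes; 0.9 at ~30x pooled depth tolerates
roughly one stray read per site while still requiring near-fixation.

### Windowed score and peak

The score of a genomic window is 100 x (mutant-specific homozygous sites) /
(sites observed in the window). Using the observed-variant denominator
(rather than window length or genome-wide counts) makes the score robust to
uneven exome capture density and bounds it in [0, 100]. Windows are sliding
by default (1 Mb wide, 100 kb step; tiled windows are one `step` setting
away) and windows with fewer than `minVariants = 5` sites are excluded from
peak search to suppress low-coverage artifacts. The peak is the union
interval of all eligible windows attaining the maximum score; when every
eligible window scores zero the peak is undefined rather than arbitrary.

### Candidate screening

Within the peak, mutant-specific homozygous variants are classified with
precedence essential_splice > nonsense > missense > synonymous > intronic >
intergenic. Essential splice sites are the two intronic bases at each intron
end on the coding strand (canonical GT donor / AG acceptor); coding
consequences come from splicing the exons, substituting the allele, and
translating the affected codon with the standard nuclear code (stops TAA,
TAG, TGA). Only nonsense and essential-splice variants survive the screen.
Exons are stored in genomic order for both strands; reverse complementation
happens once, at coding-sequence extraction.

A donor-site lesion typically causes intron retention. `retentionConsequence`
continues the reading frame from the upstream exons into the retained intron
and reports the first in-frame stop codon, its genomic position, and the
truncated protein length in codons; if the frame runs through the intron
without a stop, no PTC is reported rather than scanning into downstream
exons (the retained-intron transcript is the molecule of interest).

## The cross simulator

`simulateCross` emulates the mapping experiment's statistical structure:

- Both F1 parents are heterozygous carriers sharing the mutagenized founder
  haplotype; every background variant's alternate allele rides that
  haplotype. This one mechanism reproduces the mutant-specific homozygosity
  enrichment that BSA exploits; ENU-private and strain variants segregate
  identically at pool level, so a single density parameter covers both.
- Gametes carry Poisson crossover counts (mean `recombRate` per chromosome,
  default 1) placed uniformly, without interference — irrelevant at 1-Mb
  window resolution.
- Larvae homozygous for the causal allele form the mutant pool; a same-size
  sample of the rest forms the sibling pool. Larvae are simulated until the
  mutant pool fills (about 4x the pool size, as expected for a recessive
  allele), never silently under-filled.
- Per-site pool depths are Poisson (default mean 30) and alternate counts
  binomial at the pool allele frequency.

Defaults are the study conditions: 20 larvae per pool, 5 chromosomes of
25 Mb, one background variant per 50 kb (an exome-scale SNV list). The
synthetic genome is a periodic ACGT backbone carrying a realistic causal
locus: 13 coding exons of 120 bp, GT..AG introns, a G-to-A lesion at the
donor of intron 12, and an in-frame TAA two codons into the retained
intron. The backbone is not a realistic sequence away from the locus — it
only has to supply reference bases for variant sites — so classification
tests away from the causal gene exercise coordinates, not biology.

What the simulator does *not* model: reference bias and mapping artifacts,
depth heterogeneity of exome capture, crossover interference, and linked
selection. Passing recovery tests therefore demonstrate the statistical
machinery, not robustness to alignment pathology.

`countRecombinants` scores each mutant-pool gamete's haplotype origin at a
marker versus the lesion; 225 mutant larvae give 450 scorable meioses, and
a marker at the lesion shows zero recombinants by construction.

## Expression quantification

FPKM is computed exactly as
`F_gene * 1000 * 1e6 / (F_allexon * L_gene)`, with `L_gene` the unique
exonic length and `F_allexon` the per-sample column sum — identical by
construction to "total exonic fragments" when counts are exon-union gene
counts, which is the input contract (paralog collapse happens at counting
time, upstream of the table). The identity
`sum(FPKM * L) / 1e9 = 1` per sample is asserted to 1e-9 in the tests.

Differential calls use pure fold change; with one library per condition no
replicate-based statistic is available, and none is emitted (a documented
limitation, not an omission). A pseudocount `epsilon` (default 1e-6 FPKM)
keeps log2 fold changes finite when one side is zero; such records are
flagged `zero_side` rather than silently clamped, since a "fold change" of
-32 is an artifact of epsilon, not a measurement. The expressed filter is
strict: FPKM > 0.1 in both samples.

The count simulator plants class-structured effects mirroring the screen's
observations: apoptotic genes up ~ +4, spliceosome components up ~ +3.7, a
moderate down class ~ -2.7, vision genes collapsing to zero mutant
expression (planted log2 fold changes spread over -17 to -7), and one
upregulated causal gene (+3.35). The wild-type baseline is a uniform 100
fragments per gene: isolating fold-change structure from expression-level
structure keeps the zero-dispersion limit exact and makes recovery errors
attributable. Negative-binomial dispersion defaults to 0.05 (typical for
larval pools); at dispersion 0 counts equal their rounded means.

Recovery is assessed per planted class, pooling estimates across a 10-seed
sweep: single-gene classes have per-seed sampling noise of ~0.5 log2 units
at this depth and dispersion, so only the pooled class mean is a stable
estimand. Pooled class means recover within ±0.3; the residual error is
dominated by a small negative composition bias — planted upregulation
inflates the mutant library total, shifting every FPKM ratio slightly down —
which is a property of the estimator, not the simulator.

## Junction screen

Junction counts are normalized to RPM per sample (each sample sums to 1e6).
A junction is *known* only when the interval it skips equals an annotated
intron exactly; boundary-to-interior junctions, the signature of intron
retention, are novel. The candidate filter is the conjunction of four
strict predicates: mean log2(rpm + c) > 2, |log2 ratio| > 2, pseudocounted
fold change > 4, and mean RPM > 4 — the two stated threshold cascades are
both applied, the conservative reading when both are described as applied.
The absolute ratio makes the screen symmetric in sample order, so lost
junctions are candidates alongside gained ones. The pseudocount c = 0.5 RPM
keeps logs finite at zero; "average intensity" is the mean of logs by
default with log-of-mean available via `intensityMode`, since either
reading is defensible. Upstream low-count filtering (a voom-style step in
the original toolchain) is replaced by a minimum of 5 fragments in at least
one sample; RPM is the normalization actually used for candidate selection,
so no linear-model normalization is reimplemented.

The simulator plants retention junctions at the causal gene's retained
intron boundaries in the mutant only, at a configurable fraction (default
0.2) of the gene's junction coverage, and removes the same fraction from
the canonical junction. At the default causal upregulation the retention
junctions clear all four thresholds with margin; at low causal expression
the intensity threshold is the binding constraint, which is exactly the
behaviour the screen is designed to have.

## qPCR quantification

ddCt uses ideal doubling efficiency: dCt = mean Ct(gene) - mean Ct(reference)
per sample, ddCt = dCt(test) - dCt(calibrator), fold = 2^-ddCt, and the
reference-zero normalization is fold - 1 (the reference gene sits at 0,
positive means up). The standard error treats each replicate index as one
independent round of the *full* statistic — the natural reading of "mean of
3 rounds using standard error" — rather than propagating per-term errors;
rounds missing any of the four Ct values are dropped with a warning.
Identities (self-calibration fold 1, reciprocal folds multiplying to 1) are
asserted to 1e-12.

Phenotype proportions (rescue scoring) are binomial point estimates with
Wilson score intervals — well-behaved at 0% and 100%, unlike Wald.

## Problem sizes and numerical choices

The test and acceptance runs use 20-seed sweeps of the default 5 x 25-Mb
cross, a 10-seed sweep of 2000-gene expression simulations, and a 20-seed
sweep of 500-gene junction simulations — sizes at which the recovery rates
are stable while a full run stays in the minutes range on one core.
Tie-breaks are deterministic throughout: peak ties take the union interval,
ranking ties order by gene id, and junction candidates sort by absolute
log2 ratio. Degenerate inputs error early and explicitly: empty libraries,
zero-length genes, missing reference genes, and out-of-range coordinates
are contract violations, not NA propagation.

## Known limitations

- One transcript per gene; no UTR model (non-coding intragenic positions
  classify as `intronic`), no regulatory annotation.
- No read-level simulation or alignment; the pipeline begins at variant
  calls and count tables, where the bespoke computation begins.
- Pure fold-change differential expression carries no error control; the
  package deliberately emits no p-values for it.
- The ddCt model fixes amplification efficiency at 2; no standard-curve
  correction.
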