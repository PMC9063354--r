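---
title: "Methods: nascent transcription, enhancer RNAs, and subgenome bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nascent transcription, enhancer RNAs, and subgenome bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernascape)
```

## The problem

Large plant genomes such as hexaploid bread wheat carry most of their
regulatory information in intergenic space. Nascent RNA assays (GRO-seq,
pNET-seq) record where RNA polymerase II is engaged, regardless of transcript
stability, so they reveal unstable intergenic transcripts — including
enhancer RNAs (eRNAs) — that steady-state RNA-seq misses. `ernascape`
implements the downstream analysis: from strand-specific polymerase 5'-end
positions to a catalog of transcribed enhancers, their target genes, and the
relationship between subgenome-biased enhancer transcription and homoeolog
expression dominance. Everything is exercised end to end on a synthetic
hexaploid toy genome with planted, machine-readable ground truth.

## Signal model

The primitive is a **strand track**: sparse per-base counts of read 5' ends
(the engaged-polymerase position) per strand, normalized to events per
million mapped reads. Per-million normalization makes replicate tracks of
different depth directly comparable; it preserves zeros and relative ratios
exactly. Replicate agreement is the Pearson correlation of strand-summed
densities in 500-bp bins tiled from position 0 (the final partial bin
included); depth-scaling a track leaves the correlation unchanged. Replicates
are then pooled by position-wise count summation for all quantification.

Quantification windows (`window_signal()`) sum density in an inclusive
`±flank` window around an anchor, strand-restricted where the analysis is
strand-aware; `metaprofile()` bins the same densities around anchor sets,
flipping minus-strand anchors so downstream always reads to the right.

## TSS calling and clusters

Detection is a genome-wide Poisson background test: with a strand's mean
per-base rate $\lambda$ (total strand events / genome length), the threshold
$k^\*$ is the smallest count whose upper tail $P(X \ge k \mid \lambda)$ is at
most $\alpha$ (default $10^{-6}$), combined with an absolute floor
`min_count = 5`. Candidates closer than 50 bp on one strand collapse to the
strongest position (ties to the left), so one sharp initiation site gives
one call. Both knobs are exposed; the test suite pins $k^\*$ against direct
tail summation.

Calls within 3 kb of one another on a strand chain into **TSS clusters**
(single-linkage, not fixed windows), whose 5' end is the cluster TSS. A
cluster from the merged track is kept only when *every* replicate contributes
a call inside its span on the same strand — the conservative reading of an
all-replicates filter; a signal-based alternative was considered and
rejected because it would re-admit the noise the filter exists to remove.
Cluster transcription (`signal_250`) is the ±250 bp density at the TSS on
the cluster strand, the quantity used for decile grouping (descending
signal, remainder spread over the top groups, coordinate tie-breaks).

## Intergenic annotation and enhancer classification

Clusters overlapping any gene body (high or low confidence) ±1 kb —
strand-agnostic — are genic-proximal; remaining clusters overlapping the
coding-transcript mask are excluded; the rest are intergenic. Read-category
fractions assign each event one label with priority
exon > intron > TSS1K > TES1K > intergenic so genic signal is never double
counted; TSS1K/TES1K are strand-aware 1-kb windows at the gene ends.

Enhancer-like elements are merged runs of chromatin states 5–7 (open,
acetylated, CpG-rich states in the 15-state wheat segmentation) lying at
least 3 kb edge-to-edge from the nearest gene body. Gene-body distance (not
TSS distance) is used; the choice is configurable. An element is
*transcribed* when ≥1 intergenic cluster overlaps it on either strand. The
more active strand — ±250 bp density at the strongest overlapping cluster's
TSS per strand — is *primary* (ties to `+`). Bidirectional (BE) requires
called clusters on both strands; this reuses the replicate-filtered
detection machinery instead of inventing a secondary-signal threshold. For
unidirectional (UE) elements the secondary signal is measured on the
opposite strand at the primary anchor, which keeps the primary ≥ secondary
ordering by construction on any data where detection precedes signal.

## Target assignment

Candidate genes within 500 kb (edge-to-edge, same chromosome) of a
transcribed enhancer are tested on two criteria: (i) Pearson correlation
≥ 0.7, across panel samples, between the strongest histone/DNase peak
overlapping the enhancer and the strongest peak overlapping the gene's
promoter (1 kb up / 500 bp down of the TSS, strand-aware), computed per mark
with a pair passing if *any* mark passes; (ii) at least one Hi-C read pair
connecting enhancer and promoter in either anchor orientation. Only when no
candidate passes within 500 kb does the search expand to 2 Mb under the
same criteria. "Strongest peak" means maximal mean signal; pairs without an
overlapping peak, or with a zero-variance vector, fail the correlation
criterion rather than defaulting. Output ordering is deterministic and
independent of input order.

## Subgenome bias and the odds ratio

For one subgenome pairing, homoeolog groups with exactly one gene on each
side form 1:1 pairs; a gene counts as enhancer-associated only if a linked
transcribed enhancer lies on its own chromosome. Discordant pairs (exactly
one side associated) feed a 2×2 table whose rows split pairs by which side
bears the enhancer and whose columns record whether the first subgenome's
homoeolog is the dominant one. Dominance is a fold-change gate (default
2.0) with a minimum-expression floor (0.5) guarding zero-expression
artifacts; a per-pair significance test is not modelled because the
expression inputs carry no per-pair replication. Because each pair lands in
exactly one row, the rows are independent samples, and the Woolf standard
error $\sqrt{1/a + 1/b + 1/c + 1/d}$ with a Haldane–Anscombe 0.5 correction
(applied only when a zero cell occurs) gives calibrated Wald intervals —
this is why the rows are defined on disjoint pairs rather than mirroring the
same pairs into both rows, which would correlate the rows and invalidate the
classical SE. The three pairings pool by summing tables.

## Auxiliary statistics

*Nucleotide diversity.* Per biallelic SNP,
$\pi_{site} = 2j(n-j)/(n(n-1))$ over called haplotypes; window $\pi$ is the
per-site sum divided by the window length (500 bp tiling from 0), matching
the `--window-pi` convention of standard VCF tooling. Missing genotypes
reduce $n$ per site; multiallelic records are skipped and counted. The eRNA
vs intergenic comparison samples length-matched random regions uniformly
from gene-free space, seeded, with a per-subgenome breakdown.

*Coverage saturation.* Nested seeded subsamples (smaller ⊂ larger) at each
requested size; a 10-kb bin is covered at ≥5 reads. Nesting makes the curve
non-decreasing and convergent to the full-data covered fraction; an
independent-draws mode exists for sensitivity checks.

*Reporter scoring.* Activity (relative intensity) is Fluc/Rluc normalized to
the blank construct, so the blank is exactly 1; constructs at ≥2.0 are
positive (the cutoff sits above a negative control at 1.6). Correlations
between activity and region signal remove points outside median ± 3·MAD on
either variable — a concrete, logged rule standing in for the informal
removal of extreme outgroup points.

## The synthetic study

`sim_config()` defaults define the study conditions: 3 subgenomes × 1
chromosome × 5 Mb, 100 homoeolog triads (non-overlapping genes with 2–6
exons at jittered syntenic positions, log-normal triad-correlated
expression), 200 enhancer-like elements ≥3 kb from genes (50% transcribed,
35% of those bidirectional), a sharp initiation spike (80% of eRNA reads at
the exact TSS, mean 30 reads per strand per replicate scaled by a per-element
strength in [1, 2.2], secondary strand at 0.7×), genic reads mixing a
TSS-proximal pausing spike (weight 0.4) with exon-biased body reads (3:1),
uniform background at 2×10⁻⁴ events/bp/strand, 4 replicates. These depths
follow the planted-TSS-at-≥20-reads regime the recovery tests assume.
True enhancer–target pairs (1–2 genes ≤500 kb; 10% of enhancers instead get
a single target at 0.6–1.9 Mb to exercise the expansion tier) share a latent
peak-panel factor — promoter-side noise is stored so the panel can be
rebuilt at any noise SD with common random numbers, making noise sweeps
deterministic — and are guaranteed ≥1 Hi-C read pair; decoy Hi-C support is
off by default, so noise-free link recovery is exact. Target genes receive a
2× expression boost, which induces the dominance association measured by
the pipeline; exact odds-ratio planting is done at the record level by
`simulate_discordant_pairs()`, which solves the dominance-outcome
probabilities (balanced fraction fixed at 0.4) so the population OR of the
implemented table equals `planted_or` — the estimator-level calibration is
therefore non-circular. Variants are planted at a rate calibrated to an
expected per-site π of 0.003, thinned 50% inside eRNA elements, over 20
diploid samples with a uniform folded frequency spectrum.

What the generator does *not* emulate: sequence content (no FASTA, no
motifs), mappability artifacts, overdispersed biological replicate
variation, 3D-contact distance decay, linkage disequilibrium, or annotation
errors. Passing recovery tests therefore demonstrates correctness of the
algorithms under their stated assumptions, not robustness to every
real-data pathology.

## Numerical choices and degenerate inputs

Coordinates are uniformly 0-based half-open internally (GFF3 converted on
read, BED passed through); one shared base counts as overlap everywhere.
Poisson thresholds come from `qpois` and are test-pinned against direct
summation. Zero-variance vectors, pairs without overlapping peaks, and
correlations on fewer than 3 points return `NA` sentinels rather than
errors mid-pipeline; empty tracks and all-zero tables are hard errors.
Deciles, cluster merging, and link output all have deterministic
coordinate-based tie-breaks. Problem sizes in the test suite (5 Mb
chromosomes, 300 planted TSSs, 200 calibration replicates at n = 5,000
pairs) were chosen as the smallest scales at which the recovery and
calibration statistics are stable.

## Known limitations

The TSS detector is a transparent Poisson model, not a reimplementation of
any published caller's internals; on real data with locally elevated
background its false-positive behaviour will differ. BE/UE classification
depends on detection power on the secondary strand, so shallow libraries
bias toward UE. The odds ratio conditions on the discordant set and the
fold-change gate; it is not a triad-level dominance taxonomy. Hi-C support
uses raw read pairs with no matrix normalization or distance-decay
correction.
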