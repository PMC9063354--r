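# ernascape

Nascent-transcription analysis for large polyploid plant genomes: from
strand-specific RNA polymerase II 5′-end signal (GRO-seq / pNET-seq style
data) to a catalog of transcribed enhancers, their target genes, and the
association between subgenome-biased enhancer transcription and homoeolog
expression dominance.

It is written for regulatory genomicists working on hexaploid bread wheat
and similar genomes, where most regulatory elements are intergenic and
their transcripts (eRNAs) are too unstable for steady-state RNA-seq.

## What it computes

Given per-replicate single-base read 5′-end positions (BED6), a gene
annotation (GFF3), a chromatin-state segmentation, a coding-transcript
mask, histone/DNase peak panels, Hi-C contacts (BEDPE), a population VCF,
and reporter-assay measurements, the package:

1. builds depth-normalized strand tracks (events per million) and checks
   replicate agreement in 500-bp bins;
2. calls TSSs against a genome-wide Poisson background
   (threshold *k\** = smallest count with upper tail ≤ α), chains calls
   within 3 kb into TSS clusters (TCs), and keeps only clusters supported
   by **all** replicates;
3. classifies TCs as genic-proximal (gene ± 1 kb), masked, or intergenic;
4. derives enhancer-like elements from chromatin states 5–7 lying ≥ 3 kb
   from genes, labels them transcribed/untranscribed by intergenic-TC
   overlap, and splits transcribed ones into bidirectional (BE) and
   unidirectional (UE) with a primary (more active) strand;
5. links transcribed enhancers to target genes within 500 kb that pass a
   histone-signal correlation cutoff (Pearson r ≥ 0.7 across panel
   samples) **and** ≥ 1 supporting Hi-C read pair, expanding to 2 Mb only
   when nothing passes;
6. builds 1:1 homoeolog pairs per subgenome pairing and measures, over
   discordant pairs (enhancer on one side only), the odds ratio

   OR = (a/b)/(c/d)

   between "which homoeolog bears the enhancer" and "which homoeolog is
   dominant" (fold-change gate, default 2×), with Haldane–Anscombe
   correction and a Wald 95% CI from SE(log OR) = √(1/a+1/b+1/c+1/d);
7. computes windowed nucleotide diversity
   π_site = 2j(n−j)/(n(n−1)) summed per 500-bp window, compares eRNA
   regions against length-matched random intergenic regions, builds
   coverage-saturation curves (10-kb bins, ≥ 5 reads = covered), and scores
   dual-luciferase reporter constructs (activity relative to blank;
   positive at ≥ 2.0).

A fully seeded synthetic hexaploid study (`sim_config()`,
`simulate_erna_study()`) generates every input with planted ground truth,
so the whole pipeline is testable offline.

## Worked example

```r
library(ernascape)

cfg <- sim_config(seed = 7, chrom_length = 2e6, n_triads = 40,
                  n_enhancers = 60)
sim <- simulate_erna_study(cfg)

res <- run_erna_analysis(sim$reads, sim$genome$layout, sim$genome$genes,
                         sim$landscape$states, sim$landscape$coding_mask,
                         sim$landscape$panel, sim$landscape$contacts)

res$track
#> <nascent_track> 41,055 events at 27,973 positions on 3 chromosome(s)

table(res$tcs$genomic_class)
#> genic_proximal     intergenic         masked
#>             63             37              5

table(res$enhancers$status, res$enhancers$dir_class)
#>                 BE none UE
#>   transcribed    7    0 23
#>   untranscribed  0   30  0

dplyr::count(res$links, search_tier)
#>   search_tier       n
#> 1 expanded_2Mb      5
#> 2 primary_500kb    36
```

The merged track pools four replicates. Of the replicate-consistent TSS
clusters, 37 are intergenic; 30 of the 60 planted enhancer-like elements
are transcribed (7 bidirectional, 23 unidirectional), matching the planted
truth exactly, and 41 enhancer–gene links are recovered (5 through the 2-Mb
expansion tier).

```r
pairs <- purrr::map(list(c("A","B"), c("A","D"), c("B","D")), \(sg)
  bias_call(build_homoeolog_pairs(sim$genome$genes,
                                  sim$landscape$expression, res$links, sg)))
merged_dominance_or(pairs)
#> Odds ratio: 41.121 (95% CI 2.274-743.522) [Haldane-corrected]
#>       outcome
#> group  yes no
#>   row1  11 16
#>   row2   0 29
```

Enhancer-bearing homoeologs dominate their partners far more often than
enhancer-free ones — as expected here, since the simulation plants a 2×
expression boost on true target genes (the wide CI reflects the small
discordant set at this toy scale).

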