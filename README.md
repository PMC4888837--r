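# damidscope

DamID-seq analysis for chromatin-binding studies: GATC-anchored read
filtering, control-normalized variable-width peak calling, factor
co-occupancy at promoters, TSS metaprofiles, and knockdown
expression-concordance — with a self-contained simulator providing ground
truth for every stage.

## Who it is for, and the problem it solves

DamID tethers *E. coli* Dam methylase to a protein of interest (here, the
motivating application is nucleoporins such as Nup98 and soluble Pom121
binding chromatin away from the nuclear pore). Dam methylates adenines in
GATC motifs near the protein's binding sites; sequencing the released
fragments reads out where the protein touched the genome. The analysis
differs from ChIP-seq in three load-bearing ways, all implemented here:

1. **GATC anchoring.** Informative reads start at GATC fragment
   boundaries. A read is kept only if it aligned uniquely (MAPQ > 10) and
   its strand-aware five-prime end coincides with a GATC cut site.
2. **Duplicates are signal.** Most reads pile onto a limited number of
   GATC sites, so duplicate reads are retained, not removed.
3. **Enrichment is relative to Dam-GFP.** A free-Dam (GFP fusion) library
   measures background methylation. Per-cut-site counts are scaled to
   **normalized reads per 10 million** (`10^7 / N` per read), and a peak —
   a gap-limited run of enriched cut sites — must contain at least
   **50 normalized reads** and **2-fold** more normalized reads than the
   identically processed control:

   peak kept ⇔ s ≥ 50 and (s + 1)/(c + 1) ≥ 2

   with s the sample and c the control normalized-read sum over the
   region, in reads-per-10-million units.

Downstream, peak sets from two factors are compared as merged clusters
(mergePeaks-style Venn counts), assigned to promoter windows
(−1000/+100 bp around the TSS), profiled as peak density per bp per gene
around TSSs, intersected with a third factor's peaks (fractional
overlap), and related to knockdown RNA-seq through misregulated-gene
overlap (hypergeometric) and sign-concordance of log2 fold changes.

## Worked example

Simulate a small study — two factors sharing half their target promoters,
an NPC-detached variant bound at a subset of the shared ones, and a
Dam-GFP control — then run the analysis:

```r
library(damidscope)

cfg <- sim_config(seed = 11, chrom_length = 300000L, n_genes = 60L,
                  n_targets_a = 15L, n_targets_b = 15L,
                  reads_per_library = 30000L)
exp <- simulate_damid_experiment(cfg)

peaks <- lapply(c(A = "A", B = "B", deltaCTD = "deltaCTD"), function(f)
  call_damid_peaks(exp$reads[[f]], exp$reads$control, exp$index, label = f))
peaks$A
#> DamID peak set 'A': 15 peak(s)
#>   width: median 946 bp [573-1041]; norm_reads: median 366666.7; fold: median 9.72

ov <- overlap_peaksets(peaks$A, peaks$B)
ov
#> Peak-set overlap (A vs B), merged-cluster counts:
#>   A only: 7
#>   shared: 8
#>   B only: 7
#>   raw peaks in shared clusters: 8 (A), 8 (B)

cobound_promoter_count(ov, exp$genome$genes)
#> [1] 8
#> attr(,"n_genes")
#> [1] 8

fraction_overlap(ov, peaks$deltaCTD)
#> 4 of 8 clusters (50%) overlap the comparison set

direction_concordance(exp$de$a, exp$de$b)
#> Direction concordance (padj < 0.05 in first table): 0.857 (6 of 7 genes; 0 zero-fold excluded)
```

Reading the numbers: all 15 planted target promoters of factor A come
back as peaks; 8 merged clusters are bound by both factors (the planted
cobound fraction here is 0.5 of 15 ≈ 8), all 8 sit at promoters; 4 of the
8 shared clusters are also bound by the variant; and of the genes
significantly misregulated in knockdown A, 86% move in the same direction
in knockdown B (the generator's concordance default is 0.8).

The same analysis runs from one configuration with
`run_damid_pipeline(config, out_dir)`, which writes counts TSVs,
bedGraphs, peak BED/TSVs, a Venn summary, TSS-profile TSVs, the paired
fold-change table, and a JSON manifest.

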