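---
title: "Methods: DamID-seq peak calling and co-occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DamID-seq peak calling and co-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damidscope)
```

## The measurement model

DamID fuses a chromatin protein of interest to *E. coli* Dam methylase.
Wherever the fusion protein contacts chromatin, nearby adenines within GATC
motifs are methylated; digestion at methylated GATC sites releases
fragments that are amplified and sequenced. Two consequences shape the
whole analysis:

* **Reads are GATC-anchored.** Genuine DamID fragments begin at a GATC
  boundary, so the five-prime end of an informative read coincides with a
  GATC cut site. Reads aligning elsewhere are predominantly nonspecific
  noise and are discarded.
* **Background is non-zero everywhere.** Free Dam methylates accessible
  chromatin indiscriminately. A Dam-GFP fusion measures this background,
  and every enrichment statement is made *relative to the identically
  processed Dam-GFP control*.

Because a handful of GATC fragments near a true binding site soak up many
reads, duplicate reads are genuine signal in DamID and are **retained** —
the reverse of the ChIP-seq convention.

## Coordinates and units

All intervals are 0-based, half-open internally and in the BED/bedGraph
files the package writes; 1-based display happens only in printing. The
modeled fragment boundary is `motif_start + cut_offset` with
`cut_offset = 2` by default (GA^TC, the DpnI-relevant boundary); the
offset is a parameter because "just downstream" of a motif is not a single
number.

Counts are expressed in **normalized reads per ten million**: per-cut-site
raw counts scaled by $10^7/N$ where $N$ is the library's retained read
count. All peak thresholds are stated in this unit, so libraries of
different depth are directly comparable. A normalized track always sums to
$10^7$.

## Read filtering

A read is retained iff

1. mapping quality is strictly greater than `mapq_min` (default 10), the
   uniqueness proxy applied uniformly to all libraries; and
2. its strand-aware five-prime end (alignment start on `+`, last aligned
   base on `-`) lies within `anchor_tolerance` bp (default 0, i.e.
   exactly) of a GATC cut site.

When `anchor_tolerance > 0` and two cut sites are equidistant, the
leftmost site wins — a deterministic tie-break. Duplicates are kept by
default (`keep_duplicates = TRUE`). Reverse-strand anchoring at the
five-prime end (rather than the alignment start) is a modeling choice: the
fragment boundary a read attests to is where sequencing started.

## Peak calling

Peaks are variable-width unions of enriched GATC cut sites, filtered by
two deterministic thresholds:

* at least `min_norm_reads = 50` normalized reads per peak (per ten
  million reads sequenced), and
* at least `min_fold = 2` fold more normalized reads than the Dam-GFP
  control, computed per region as
  $(s + c_0)/(c + c_0)$ with pseudocount $c_0 = 1$ normalized read
  guarding control-empty regions. The sample sum $s$ runs over member cut
  sites; the control sum $c$ runs over **all** cut sites inside the
  region span, so a region is penalized for background it happens to
  bridge across.

**Candidate grouping.** Member sites are grouped into maximal runs with
consecutive members at most `max_gap = 1500` bp apart (about six times the
~256 bp expected GATC spacing). Regions span their outermost member sites;
an optional symmetric `pad` (default 0) widens them. Candidates never
cross chromosomes.

**Site membership.** With no control track, a member site is simply a
covered site (value > 0). When a control is available — the normal case —
a site must additionally be *site-level enriched*:

$$\frac{v + c_0}{\max(c_v,\ \bar c) + c_0} \ge \texttt{min\_fold}$$

where $v$ is the sample value at the site, $c_v$ the control value, and
$\bar c$ the control's genome-wide mean per covered site. The floor at
$\bar c$ encodes the expected background density: a site whose control
happens to be empty by sampling noise must still beat the background a
correctly behaving control would show there. Without this, in deeply
covered genomes (several reads per site on average) every cut site is
covered, covered-site runs coalesce into chromosome-scale candidates, and
planted signal is diluted below any fold threshold; conversely at shallow
depth, bare fold-vs-local-control lets ~20% of background sites through
by Poisson noise alone. The floored site test keeps background member
rates near zero in both regimes while leaving genuinely enriched
promoters (tens of fold above background) untouched. This is the
deterministic analogue of the expected-background tag models used by
HOMER-class callers; no Poisson/FDR machinery is layered on top because
the published thresholds are deterministic.

**Minimum support.** An emitted peak must cover `min_sites = 3` member
cut sites (at least two GATC fragments). The 50-normalized-read floor
suppresses single-site noise only when coverage per site is well below 50
normalized reads, which holds for genome-scale libraries (a 10M-read
human library averages ~1.4 reads per GATC site) but not for the compact
genomes the simulator builds. Requiring multi-fragment support is the
corresponding scale-free guard: an isolated single fluctuating fragment
never becomes a peak.

One stated monotonicity caveat: the number of *candidates* is
non-increasing in `max_gap` (regions only merge), but the number of
*emitted* peaks need not be — merging two subthreshold runs can lift
their union over the 50-read floor. The property tests assert the
former.

## Co-occupancy, promoters, TSS profiles

Two peaks overlap iff their half-open intervals share at least 1 bp;
touching boundaries do not count. Venn counting follows mergePeaks
semantics: connected components of the overlap graph across both sets are
*merged clusters*, a cluster containing members of both sets is shared,
and raw-peak tallies are reported alongside for transparency.

A promoter is the strand-aware window `upstream = 1000` bp before to
`downstream = 100` bp after the TSS (the last base of the gene interval
on the minus strand). A cobound promoter is a shared cluster intersecting
at least one promoter window; because "co-occupied promoters" could also
be counted per gene, the distinct-gene count travels along as an
attribute.

The TSS metaprofile reports peaks per base pair per gene in bins
(default 250 bp over ±10 kb): each (gene, peak) pair increments every bin
its TSS-relative, strand-oriented interval intersects, and the bin count
is divided by `bin_width × n_genes`. A midpoint mode (each pair counts in
exactly one bin) is available; interval mode is the default because peak
width is informative in DamID. `fraction_overlap()` reports the
percentage of shared clusters also covered by a third factor's peaks —
with the published counts (580 of 1056 cobound regions also bound by the
NPC-detached variant) it prints 55%, the worked example the acceptance
script recomputes.

## Knockdown concordance

DE tables (gene, log2 fold change, p, adjusted p) are taken as given;
model fitting is upstream of this package. The misregulation overlap uses
strict thresholds (`p < 0.01`; `padj < 0.05` for the quadrant analysis)
within the *intersection* gene universe of the two tables, and attaches an
exact upper-tail hypergeometric probability — descriptive only, never a
filter. Direction concordance selects significant genes from the first
table and reports the fraction whose fold change agrees in sign with the
second table; genes with a fold change of exactly zero in the comparison
table carry no direction and are excluded from both numerator and
denominator.

## The simulator and what it does (not) show

`simulate_damid_experiment()` generates: a random genome with GATC motifs
planted at geometric gaps (mean 256 bp, the genome-wide expectation for a
4-mer; incidental motifs arising in the random background — about another
1/256 per bp — are left in place, so realized spacing is roughly half the
nominal setting); non-overlapping fixed-length genes with random strand;
per-factor read libraries whose five-prime ends sit exactly on cut sites,
with sites inside target promoter windows weighted `enrichment_fold`
(default 20) relative to background and the Dam-GFP control sampling
uniformly; a 10% duplicate re-emission rate; and a pair of DE tables in
which shared-target genes carry true effects agreeing in direction with
probability `de_concordance` (z-score effects of magnitude
$|N(4, 1)|$, two-sided normal p-values, Benjamini-Hochberg adjustment —
the conventional default where the original adjustment is unstated).

Default study conditions — one 1 Mb chromosome, 200 genes, 50 target
promoters per factor, cobound fraction 0.5, variant subset fraction 0.55,
100,000 reads per library — are the regime the recovery benchmarks run
at: 20 replicates give sensitivity ≥ 0.95 at false-discovery proportion
≤ 0.05, and the cobound/variant fractions and the direction-concordance
parameter (over c ∈ {0.5, 0.8, 1.0}, 2,000 genes) are recovered within
±0.05 and ±0.03 respectively. The concordance benchmark uses 500 targets
per factor at cobound fraction 0.8 so the binomial error of the per-seed
estimate is small against the ±0.03 band.

What passing these benchmarks does **not** show: the simulator has no
alignment error, no mappability structure, no fragment-length
distribution, no chromatin-accessibility covariate on background
methylation, and error-free single-end reads. Real Dam-GFP background is
accessibility-correlated rather than uniform, so real-data peak calls
depend on the control more delicately than the uniform-background
recovery rates suggest. The simulator validates the pipeline's logic, not
the biology of any particular library.

All generator stages draw their streams through `derive_seed(seed,
stage)`, so adding or rerunning a stage never perturbs another stage's
randomness, and every output is a pure function of (config, seed).

## Numerical and degenerate-input choices

* Normalization requires a non-empty retained library (`"empty library"`
  error); closure to $10^7$ is exact up to floating error (tested at
  1e-6 relative).
* An empty control track downgrades scoring to a zero control with a
  warning rather than failing, per the stated contract.
* Equidistant anchor ties go to the leftmost cut site; `round()`-style
  reporting uses half-up rounding so printed percents are stable.
* N runs in the genome never match the motif scanner and are skipped
  silently; lowercase bases match (masking is treated uniformly —
  nothing in the source data distinguishes soft-masked state).
* The fold pseudocount (1 normalized read) is deliberately in normalized
  units so its influence shrinks as libraries deepen.

## Interfaces

The package is driven from R: stage functions compose explicitly, and
`run_damid_pipeline()` executes the whole analysis from a single list or
YAML configuration, writing every intermediate as plain text (counts
TSVs, bedGraphs, peak BED/TSVs, Venn summary, profile TSVs, paired
fold-change table) plus a JSON manifest sufficient to re-run any stage.
`scripts/acceptance.R` in the repository shows the fully scripted usage.
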