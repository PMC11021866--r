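---
title: "Methods: pooled-index QTL-seq analysis in poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-index QTL-seq analysis in poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem and the statistic

Bulked segregant analysis by whole-genome sequencing (QTL-seq) localizes a
quantitative trait locus by comparing the pooled allele frequencies of the
two phenotypic extremes of a segregating population. `poolscan` implements
this for an outbred F1 design such as a fruit-tree cross: the two parents
and two DNA pools — the lines with the largest and the smallest fruit —
are sequenced, variants are called against a reference genome, and at each
biallelic site the *index* of a pool is the fraction of its reads carrying
the non-reference allele,

$$\mathrm{index} = \frac{\mathrm{alt\ reads}}{\mathrm{ref\ reads} + \mathrm{alt\ reads}},$$

with $\Delta = \mathrm{index}_{\mathrm{large}} - \mathrm{index}_{\mathrm{small}}$.
At markers unlinked to the trait both pools are random draws from the same
population and $E[\Delta] = 0$; at a causal locus the pools are enriched
for opposite QTL alleles and $\Delta$ moves away from zero. The scan is run
separately on SNP sites (SNP-index), short insertion/deletion sites
(InDel-index) and on their union (All-index).

## Site filters

Raw pooled indices are noisy at low depth and sequencing/alignment errors
concentrate at low-index sites. A site is therefore removed when and only
when (i) both pool indices are below 0.3, or (ii) both pool depths are
below 7, or (iii) the index is missing (zero depth) in either pool
(`filter_records()`). A site that fails a threshold in one pool only is
kept — the asymmetry is the signal of interest. The filter is idempotent,
and the same retention rule participates in the null simulation below,
which matters for calibration.

## Sliding-window scan

Windows of 1 Mb stepped every 1 kb (defaults; configurable) are laid along
each chromosome in 0-based half-open coordinates; starts run over multiples
of the step with `start + window <= L`, and one truncated terminal window
covers the chromosome end when the step does not divide `L - window`. A
chromosome shorter than the window yields a single whole-chromosome
window. The window statistic is the unweighted arithmetic mean of the
per-site $\Delta$ over sites in `[start, end)`; windows without sites carry
`NA` and never enter significance calling — imputing them would
manufacture signal in marker deserts.

## Null confidence intervals by simulation

There is no useful closed form for the null distribution of $\Delta$ under
pooled sampling of a finite family, so the envelope is simulated
(`simulate_null_ci()`). For a depth key $d$, each draw constructs two pools
of `pool_size` progeny under the no-QTL segregation model — under the
`"1:1"` pseudo-testcross model each line's marker dosage is Bernoulli(1/2)
out of two alleles, so the pool allele frequency is centred on 0.25 —
samples per-pool depths, draws alternate reads binomially at the pool
frequency, and computes $\Delta$. Three deliberate choices:

* **Depth dispersion.** Depths are drawn Poisson around the key by default
  (`depth_model = "poisson"`), matching the read model of the data. This
  also smooths the discreteness of the binomial $\Delta$ lattice, which is
  what lets an empirical 95% quantile behave like a 95% envelope at the
  site level; a `"fixed"` depth mode is available.
* **Filter conditioning.** Simulated draws that the site filter would
  remove are discarded before quantiles are taken (configurable via
  `min_index = NULL`). The envelope is then the null distribution of
  $\Delta$ *among retained sites* — the population actually scanned.
  Conditioning is essential: retention truncates low-index sites, inflating
  $|\Delta|$ among survivors, and an unconditional envelope is far too
  narrow for the filtered data.
* **Depth keying.** Each site (or window) is compared against the envelope
  at its rounded mean pool depth; windows can alternatively use the
  harmonic mean of per-site depths (`depth_stat`). CI tables are simulated
  exactly at the keys requested, so no interpolation is involved.

Quantiles are empirical (type 7) at $(1 \pm 0.95)/2$ and $(1 \pm 0.99)/2$
from `n_sims` draws per depth (default 10,000; values below 1,000 are
warned about). The test-suite checks that ~5% of filtered null sites fall
outside the 95% envelope, that envelopes nest across levels, and that
width decreases with depth.

A window is flagged significant when its mean $\Delta$ falls outside the
chosen envelope at its depth key (default level 0.95, matching the
published convention of calling intervals against the 95% band; an
optional absolute-$|\Delta|$ floor is off by default). Comparing a window
*mean* against a *site-level* envelope is intentionally conservative —
neighbouring sites within a window are strongly correlated through linkage
and shared pool composition, so the mean does not shrink like an
independent average, and the site-level band is the field's standard
yardstick. Overlapping or abutting significant windows are merged with no
gap tolerance (`call_intervals()`), sizes are reported in Mb as
`(end - start)/1e6`, and genes whose spans intersect an interval are
attached and counted.

The source material motivating this design mentions a calling "threshold
greater than 3.0" alongside the 95% confidence level; a $\Delta$-type
statistic is bounded by 1, so that figure cannot be a $\Delta$ threshold
and likely refers to an internal plotting statistic of the original
analysis provider. `poolscan` calls significance purely against the
simulated envelope and leaves the "3.0" uninterpreted.

## Variant annotation

Gene models are one transcript per gene (`gene_models()`), with CDS
segments carrying transcript-order ranks; coordinates are 1-based
inclusive throughout (VCF/GFF3 native), and only the window code uses
half-open arithmetic. Each variant receives exactly one location with
precedence

`exonic > splicing > intronic > upstream/downstream > intergenic`,

where *exonic* means the affected range intersects a CDS, *splicing* means
within 2 bp inside an intron boundary, and *upstream*/*downstream* are
strand-aware 1 kb flanks (both distances configurable; the defaults are
the conventional ones of ANNOVAR-style annotators). A variant that is
simultaneously upstream of one gene and downstream of another is labelled
`upstream/downstream`. Multi-allelic VCF records are split into biallelic
rows on input.

Coding consequences (`classify_exonic_effect()`): SNPs are classified by
translating the reference and alternate codon with the standard nuclear
code, reverse-complementing on minus-strand genes — synonymous,
nonsynonymous, stopgain, stoploss. For InDels, an in-CDS length not
divisible by 3 is a frameshift insertion/deletion; in-frame events are
non-frameshift unless the local codon window gains or loses a stop codon,
in which case stopgain/stoploss take precedence. The implementation is
codon-local; the test suite checks it against an independent brute-force
oracle that rebuilds the entire mutant CDS, translates both proteins and
diffs them, across 1,000+ randomized variants on both strands, and also
checks invariance of every classification under reverse-complementing the
genome, gene models and alleles. When the VCF reference allele disagrees
with the genome sequence the annotator stops with a hard error — that is a
coordinate-system fault, not a condition to paper over.

Transitions are A↔G and C↔T; everything else is a transversion. The
census (`annotation_census()`) tabulates locations (exonic split by
consequence), reports Ts/Tv to 3 decimals with an infinity sentinel when
no transversions exist, and its category counts partition the variant set.

## Candidate genes

The screen applies the consequence preference rule in tiers: tier 1 —
stopgain, stoploss, frameshift (product disrupted); tier 2 —
nonsynonymous, splice-region (product changed); tier 3 — upstream or
downstream (putatively regulatory). Tier 3 is included by default because
published candidate tables of this design are dominated by
regulatory-region loci even when coding changes are stated as preferred;
the tier labels keep the priority explicit and `include_updown = FALSE`
restores the strict rule. Records are expanded to one row per
(gene, variant), deduplicated and sorted by tier then position; screening
is genome-wide by default with an `in_interval` flag, or restricted to
called intervals. Gene descriptions come from an optional TSV sidecar —
no live database lookups.

## Phenotype statistics

`summarize_trait()` reports, per trait: parental means, the mid-parent
value $V_{MP} = (P_1 + P_2)/2$, F1 mean/SD/range, the coefficient of
variation $CV = 100\,s/\bar{x}$ (sample SD, $n-1$), the proportion of F1
lines exceeding the higher parent, the mid-parent heterosis rate
$R_{Hm} = 100\,(\bar{x}_{F1} - V_{MP})/V_{MP}$, and skewness/kurtosis. The
moment convention defaults to the classical third-moment coefficient and
*excess* kurtosis (normal = 0), with the estimator type exposed for users
who want SPSS/Excel-style small-sample corrections; no downstream result
depends on the choice. Report tables round half-up (away from zero) at 2
decimals — the convention that reproduces published table values such as
13.595 → 13.60 — while all internal arithmetic is full precision. A zero
mean makes the CV undefined and is a signalled error.

Extreme-pool screening ranks lines by single fruit weight with
deterministic tie-breaks by line id; fruit length and diameter can act as
auxiliary consistency filters (a line must sit in the same tail of each
auxiliary trait within a slack quantile), but the auxiliary screen is off
by default because no explicit rule accompanies the published design.

## The synthetic-data generator

`simulate_cross()` emulates the study conditions as defaults: 284 F1
lines, pools of 30, pool depth 40×, parent depth 14×, one QTL of 1
phenotypic SD on the largest chromosome at 31 Mb, $h^2 = 0.6$, 80% SNP
markers. Design choices:

* **Segregation.** Under the default `"1:1"` model every marker is
  heterozygous in the focal (female) parent and homozygous-reference in
  the other — the informative marker set of a pseudo-testcross, as used
  when each parent's markers are analysed as a separate testcross
  population. Expected pool allele frequency at unlinked markers is 0.25
  and every marker on the QTL chromosome is informative for the scan, in
  coupling phase with the high-value QTL allele (reference-haplotype
  phasing makes long coupling blocks the realistic arrangement). A
  `"1:2:1"` model (both parents heterozygous, frequencies centred on 0.5)
  is available.
* **Linkage.** Markers on the QTL chromosome recombine with the QTL at
  Haldane's $r = \tfrac12(1 - e^{-2d})$ using 3 cM/Mb, a typical map
  density for a compact woody-perennial genome; other chromosomes are
  unlinked background.
* **Phenotype.** $y = a\,q + g + e$ in SD units with polygenic variance
  $h^2 - a^2 v_q$ and environmental variance $1 - h^2$, so the total
  genotypic variance fraction is exactly $h^2$ and the QTL class
  difference is exactly $a$. If a single QTL alone would exceed $h^2$ the
  genetic component is rescaled to variance $h^2$; at $h^2 = 0$ the
  phenotype is independent of the genotype. Trait-scale phenotypes
  (weight g, length mm, diameter mm) are affine maps of the latent value
  with a shared size factor (loading 0.8), Gaussian throughout.
* **Reads.** Per site and pool, depth is Poisson at the configured mean
  and alternate reads are binomial at the pool's true allele frequency
  (mean pooled dosage over 2 alleles). No sequencing error by default —
  an optional symmetric error rate exists — so the analytic expectations
  used in tests are exact.

The generator writes a complete input bundle (4-sample VCF 4.2 with
AD/DP, GFF3 gene models, genome FASTA with marker reference alleles and
valid ORFs planted, phenotype TSV, truth JSON), and the whole chain is
deterministic given the config seed.

What the generator does **not** emulate: linkage disequilibrium between
background chromosomes, segregation distortion, repeat-induced alignment
artifacts, depth overdispersion beyond Poisson, multi-QTL architectures or
epistasis, and the right-skewed weight distribution of real fruit (the
latent phenotype is Gaussian). Passing recovery tests therefore show that
the statistics behave correctly under the stated design — not that any
particular real dataset would yield the same intervals.

## Problem sizes and numerical details

The test suite and the acceptance script run at desk scale chosen to keep
Monte-Carlo error small relative to the tolerances: null calibration uses
a 50 Mb no-QTL chromosome at 2,400 markers/Mb (≥ 50,000 filtered sites)
against envelopes from 20,000 draws per depth; QTL recovery uses 20
replicates of the default design (three chromosomes, 40/25/20 Mb, 100
markers/Mb); the annotation oracle runs on 1,000 randomized variants.
Fixed seeds make every stochastic check reproducible. Other conventions:
ties in ranking break by line id; `quantile(type = 7)` everywhere;
windows with zero sites are excluded rather than imputed; BED output is
0-based half-open while VCF/GFF3 interfaces stay 1-based.

## Known limitations

Single-transcript gene models (the most severe consequence is taken when
genes overlap); the parental samples are carried through the VCF but not
used for filtering (an explicit design choice — the published filters
reference only the two pools); no G′-type smoothing or Fisher-test
alternatives; two-pool designs only.
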