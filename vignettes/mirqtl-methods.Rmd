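---
title: "Methods: haplotype-dosage miRNA eQTL mapping and target-hub inference"
author: "mirqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-dosage miRNA eQTL mapping and target-hub inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirqtl)
```

# The scientific problem

Allergic airway diseases such as asthma involve granulocytic (eosinophil
and neutrophil) airway inflammation whose gene-regulatory control is
incompletely understood. microRNAs are strong candidates for that control.
`mirqtl` implements the two complementary analyses used to identify
disease-associated miRNAs in an eight-founder multiparental mouse
population (a Collaborative-Cross-type panel of recombinant inbred lines):

1. **Genetics**: find miRNAs whose lung expression is differentially
   expressed and heritable across the eight founder strains, then map the
   genomic loci (eQTL) controlling their expression in the recombinant
   lines, and narrow candidate intervals using founder ancestry.
2. **Networks**: without using genotypes, find miRNAs whose predicted
   target sites are enriched among transcripts correlated with
   inflammation phenotypes — candidate "regulatory hubs".

Every stage runs on data from the package's own generator, which
reproduces the statistical structure the analyses assume, so the whole
pipeline is testable end to end without external downloads.

# Founder screen and heritability

Founder-panel expression (log2 array scale, `FounderPanel`, a
`SummarizedExperiment`) is screened miRNA-by-miRNA with a fixed-effects
one-way ANOVA on strain (`anovaDE()`), with Benjamini–Hochberg adjustment
across miRNAs and a q < 0.05 call. Broad-sense heritability is estimated
from the ANOVA mean squares (`heritability()`) as the interclass
correlation and the coefficient of genetic determination:

$$ r_1 = \frac{MSB - MSW}{MSB + (n-1)\,MSW}, \qquad
   g^2 = \frac{MSB - MSW}{MSB + (2n-1)\,MSW}, $$

where $n$ is mice per strain; $g^2$ accounts for the doubling of additive
genetic variance under inbreeding, so $g^2 \le r_1$. With unbalanced
replicates (outlier arrays removed by hand — the package reports but never
auto-drops samples) we use the harmonic-mean $n$, standard intraclass
practice; the choice matters little at these panel sizes.

`filterExpressed()` applies two declared filters on the strain-mean
matrix: *highly expressed* = the miRNA's strain mean reaches the 80th
percentile of all miRNA strain means **within at least one strain** (the
per-strain reading of "top 20th percentile in any one strain"; a pooled
reading is the main alternative, but the per-strain wording is explicit),
and *variable* = max/min strain means differ by ≥ 1.5-fold (log2
difference ≥ log2 1.5). `selectReference()` then picks the
qPCR-normalisation reference as the non-differential miRNA whose overall
mean is nearest the grand mean of the selected set, with lexicographic
tie-breaking; `deltaCt()` converts raw Ct values to the −ΔCt scale on
which all downstream traits are expressed.

# The eQTL scan

Genotypes enter as a **haplotype dosage** array (`HaplotypeDosage`):
per line and locus, the expected number (0–2) of haplotypes from each of
the eight founders, summing to 2. The additive model at a locus regresses
the trait on an intercept plus the seven non-reference founder dosages
(the first founder, A/J in the defaults, is the reference and its effect
is 0):

$$ y = \beta_0 + \sum_{k=2}^{8}\beta_k\,d_k + \varepsilon . $$

The scan statistic is the Gaussian regression LOD,
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$. This is the standard
regression form; the upstream haplotype-reconstruction software is out of
scope (dosage matrices are inputs), and no REML variant is attempted.
The engine projects traits onto per-locus orthonormal bases (pivoted QR),
which makes multi-trait and permutation scans a single matrix product;
rank-deficient loci (a founder absent) are absorbed by the pivoting, and
`fitQtl()` flags aliased founders explicitly.

Design choices worth stating:

* **Thresholds** are per-miRNA genome-wide permutation thresholds
  (default 250 permutations); the adjusted p of a peak uses the add-one
  estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, which can
  never return 0. No FDR across miRNAs is applied — significance is
  genome-wide within each miRNA, as is conventional for per-trait QTL
  scans.
* **Support intervals** use the 1.5-LOD-drop rule: the contiguous
  qualifying run around the peak, extended by one flanking locus per
  side, since published interval bounds conventionally extend past the
  discrete qualifying markers. Intervals are 1-based and closed; the BED
  export converts to 0-based half-open.
* **Local vs distal**: local means within 10 Mb of the cognate gene on
  the same chromosome.
* **Ties** at the peak go to the leftmost locus.
* **Interval collapsing** (`collapseIntervals()`) merges consecutive loci
  whose dosage matrices are equal within a tolerance, mirroring the
  practice of averaging ancestry matrices between recombinations; merged
  dosages are element-wise means, so diploidy is preserved exactly.
* **Conditional scans** add a locus's seven dosage columns to the null
  model; conditioning on the peak itself yields LOD 0 by aliasing, which
  is the correct degenerate behaviour.

The locus-model $R^2$ is reported as the locus's narrow-sense
heritability.

# Ancestry narrowing

At a mapped peak, `groupAlleles()` orders the eight allele effects and
splits them at the largest adjacent gap (first gap on ties — a
deterministic rule; the gap magnitude is returned so users can judge weak
splits). `filterSdp()` then keeps variants whose strain distribution
pattern matches the grouping exactly: group A concordant for one allele,
group B for the other, and any heterozygous or low-confidence call
disqualifies the site (strict biallelic concordance; allowing within-group
variation at non-shared sites would only enlarge the candidate set).
`annotateSnps()` assigns surviving variants to genes within ±5 kb
(GenomicRanges overlap). `alleleGroupTest()` checks functional
distinctness of a founder allele by assigning each line to its
most-probable founder at the locus (argmax dosage, minimum dosage 1.0 —
lines without a confident single-founder call are left out) and running
Tukey's HSD over founder groups. `buildTree()` gives the supporting
phylogeny: neighbour joining on Hamming distances over shared called
sites, with Felsenstein bootstrap (SNP-column resampling, bipartition
recovery counts).

# Target-hub inference

`quantitativeTraits()` correlates each feature with `log(count + 1)`
(the pseudocount admits zero cell counts; results are insensitive to it
at these magnitudes) and applies BH at FDR < 0.1 per phenotype.
`pairOpposite()` forms the two repression-consistent pairings
(positive genes with negative miRNAs, and vice versa).

`targetScore()` scores a miRNA on a gene list by summing, over
conservation-eligible predicted sites (conserved in at least one of rat,
human, chicken by default), seed-match weights 8mer = 3, 7mer-m8 = 2,
7mer-A1 = 1, multiplied by 1.5 for each site within 35 nt of another
eligible site of the same miRNA in the same UTR. These constants are
declared configurable defaults: the enrichment calibration and power
properties the package tests are weight-agnostic, so the conclusions do
not hinge on them. Protein-interaction centrality weighting is
deliberately omitted.

`mirhub()` compares the observed score against `nNull` (default 1000)
uniform without-replacement same-size gene lists from the expressed-gene
universe (no expression or UTR-length matching — the null is "a random
gene list", the simplest defensible choice), with add-one empirical p and
BH across the tested miRNAs; hubs are called at q < 0.05.
`overlapTest()` is the upper-tail hypergeometric test for overlap between
two gene sets in an explicit universe — the universe size is a required
argument because it is a scientific choice, not a computable one.

# The synthetic-data generator

`simConfig()` fixes the study conditions; the generators derive
deterministic child seeds from one master seed, so each output is
reproducible independently of call order. The defaults emulate the
design the analyses were built for:

* 129 lines, 8 founders (A/J reference, model order C57BL/6J, 129S1/SvImJ,
  NOD/ShiLtJ, NZO/H1LtJ, PWK/PhJ, CAST/EiJ, WSB/EiJ), four replicates per
  founder in the array panel.
* A three-chromosome, 300-interval collapsed map. Real collapsed maps are
  two orders of magnitude denser; the scan statistics per locus are
  unaffected by map size, and all map-size-sensitive quantities
  (permutation thresholds) are recomputed on whatever map is used.
* Haplotype mosaics from a Markov walk: Poisson crossovers per strand per
  chromosome (mean 3, a plausible density for a multi-generation funnel
  descendant), breakpoints uniform on inter-marker gaps, uniform founder
  draws. The funnel pedigree, X-chromosome inheritance and residual
  heterozygosity are not modelled. Dosages are hard 0/1/2 calls by
  default, with an optional Dirichlet blur to mimic probabilistic
  reconstruction.
* One planted large-effect local eQTL: NOD/ShiLtJ and PWK/PhJ alleles low
  by 2 units, locus h² = 0.84 — the magnitude of the strongest observed
  local miRNA eQTL; noise is scaled so the locus explains the target
  variance fraction. qPCR noise magnitude is not an observable we can
  cite, so it is an explicit knob (`noiseSd`, default 1 on the −ΔCt
  scale), not a claim.
* Log-normal granulocyte counts (eosinophils meanlog log 6e4,
  neutrophils meanlog log 1e4, sdlog 1 — typical lavage-count scales and
  dispersion), a 10,000-gene mRNA layer with 6.74% of genes per phenotype
  correlated at |r| = 0.6 (mirroring the observed ~674 positively
  neutrophil-correlated genes in a 10,000-gene universe), and a
  TargetScan-style site table with Poisson background sites and a
  five-fold enriched planted hub miRNA.

What passing tests show — and what they do not: the generator is Gaussian
on log scales, with independent lines and markers apart from the planted
structure. Real arrays have probe effects, real qPCR has
amplification-efficiency artefacts, real populations have relatedness and
linkage beyond the mosaic model. Green tests therefore certify the
*statistical machinery* (estimator correctness, calibration, power at the
stated effect sizes), not the biology of any particular dataset.

# Numerical choices and degenerate inputs

* LOD values are clamped at 0; a constant trait scans flat at 0; a locus
  with more parameters than lines is skipped with an `NA` sentinel.
* A constant miRNA in the ANOVA screen gets p = 1 by convention with a
  warning; perfect separation gets p = 0.
* `heritability()` refuses the doubly-degenerate MSB = MSW = 0 input.
* Empirical p-values (permutation and Monte Carlo) use add-one
  estimators throughout and live on a discrete grid; uniformity checks
  acknowledge the grid.
* All equality comparisons on dosages use small absolute tolerances
  (1e-6 for diploidy, exact arithmetic elsewhere).

# Problem sizes used in the checks

The packaged statistical checks run at the design's own sizes where that
is what the property asserts (129 lines, 250 permutations, 1000 null
gene lists, a 674-gene list in a 10,000-gene universe) and at reduced
sizes where only calibration is at stake (200 null traits at 100
permutations each on a 100-locus map; null hub calibration on a 400-gene
universe with 100 null lists over 200 seeds). These sizes are the
package's own reproducibility choices and complete in well under a
minute each on one core.

# Known limitations

* The LOD is the fixed-effects Gaussian form; mixed-model relatedness
  corrections are out of scope.
* Epistatic scans are not implemented (single-locus and conditional
  scans only).
* The hub null does not match expression level or UTR length; planted
  enrichment factors below ~2 at these list sizes will not be reliably
  detected.
* `filterSdp()` demands strict biallelic concordance; sites with a third
  allele are simply dropped.
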