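---
title: "Methods: comparative genomics of CAM evolution in a congeneric genome pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of CAM evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camevo)
```

# The scientific setting

Crassulacean acid metabolism (CAM) fixes CO2 at night into malate and
decarboxylates it behind closed stomata by day. When a CAM species and a C3
species are close congeners, their genome pair is a natural experiment: the
phenotype contrast should leave signatures in gene family sizes, in the
*timing* of gene expression over the 24-h cycle, in coding-sequence
selection pressure, in circadian promoter elements, and in transposable
element (TE) activity. `camevo` implements that downstream comparative
layer for a three-genome design: two focal congeners (called F and L
throughout, for the larger- and smaller-genome species) plus an outgroup A
that polarizes gene counts.

Everything upstream — assembly, gene prediction, orthology inference, read
alignment and counting, TE discovery — is out of scope. The package starts
from a genome FASTA (soft-masked), GFF3 gene and TE models, an orthogroup
table, per-gene coverage, exon-level counts, codon-alignable CDS pairs and
a metabolite table, and fixes one internal coordinate convention (0-based
half-open) at the I/O boundary so GFF3's 1-based inclusive intervals and
BED's 0-based half-open ones can never be mixed downstream.

# Coverage-based gene-family size correction

Assemblies of heterozygous genomes retain haplotigs: both haplotypes of a
region assembled as if they were two loci. Each haplotig pair looks like a
gene duplication, but a multi-mapper-randomized alignment splits the reads
of the one biological copy between the two models, so each sits near half
the genome-wide coverage. The correction rescales each orthogroup's count
in each species by

\[ r = \frac{\sum_g \mathrm{cov}_g}{n \cdot \bar c_{sc}}, \qquad
   \hat n = \mathrm{round}(n \cdot r), \]

where \(\bar c_{sc}\) is the mean coverage of genes in orthogroups that are
single-copy in *every* species. Corrections apply only to orthogroups
containing multicopy genes. Two numerical choices the formula leaves open:

* **Integerization.** We round half away from zero (2.5 → 3), and floor the
  corrected count at 1 whenever observed genes with positive coverage
  exist — a correction should not annihilate a family that is demonstrably
  present.
* **The z-score of family-size differences** for a gene set against a
  background is computed from d = F − L as
  \((\bar d_{set} - \bar d_{bg}) / (s_{bg}/\sqrt{n_{set}})\), with negative
  values meaning larger families in species L. Only the sign semantics are
  fixed by the design; this standard-error form is our concrete choice.

On synthetic data with 20% of orthogroups haplotig-inflated per species and
10% multiplicative coverage noise, ≥95% of affected multicopy orthogroups
are corrected back to their true counts (the acceptance script measures
this; at the default conditions the observed rate is 100%).

# Diel differential expression

The experimental design is 6 genotypes × 6 time points (every 4 h over
24 h) × 2 species, with time encoded as hours after the first sampled
point. Exon counts are summed per gene; TMM factors come from edgeR
(trim 30% on M, 5% on A, reference = library whose upper quartile is
closest to the mean; factors have geometric mean 1); genes with mean
cpm < 1 are removed; TPM divides counts by exonic length in kb and rescales
each sample to 10^6.

The caller is a two-stage polynomial regression on log2(cpm + 1), in the
spirit of time-course regression tools for short series:

1. Fit \(y = \beta_0 + \beta_1 S + \sum_{k=1}^{3}(\gamma_k t^k +
   \delta_k S t^k)\) with S = 0 for the baseline species (L). An overall
   regression F-test p-value per gene is BH-adjusted; genes with adjusted
   p ≤ 0.05 continue.
2. Backward-stepwise elimination drops, one at a time, the least
   significant term above 0.05. A gene is DE iff the final model retains
   the species main effect or any species × time interaction *and* its
   R² ≥ 0.6.

Design choices: least squares on normalized values (rather than a count
GLM) matches the default workflow of the regression-based time-course
tools this mirrors and is adequate for the operating points we test;
degree 3 is the highest polynomial that a 6-point series supports while
capturing one asymmetric peak–trough cycle; R² ≥ 0.6 mirrors the
documented default of those tools. Time is scaled to fractions of a cycle
inside the design matrix purely for conditioning.

Calibration on simulated data: on 2,000 pure-null genes (rhythms shared
between species, so stage 1 fires on time effects but no species term
exists) the fraction of genes called DE stays ≤ 0.08; for planted
interactions (amplitude 1.5 vs 0 on the log scale, baseline mean 500,
negative-binomial dispersion 0.1) power is ≥ 0.9 — in practice 1.0.

DE profiles are clustered with average-linkage hierarchical clustering on
1 − Pearson distance; K is chosen by a k-means elbow — the smallest k whose
incremental within-cluster SS gain, measured against the one-cluster
dispersion, falls under 10% (cap 12). Measuring the gain against the
one-cluster dispersion rather than the previous k keeps the rule stable
when the within-SS approaches zero.

# Pairwise dN/dS

One-to-one ortholog CDS pairs are filtered (removed if both members lack a
start and/or stop codon, or if the length difference exceeds 20% of either
length — strictly "more than", so an exactly-20% pair is retained), aligned
by translating, globally aligning the proteins (BLOSUM62, gap open 10 /
extend 0.5) and back-translating gaps as codon triples. Internal stop
codons invalidate a pair (we refuse rather than repair putative
frameshifts); terminal stops are stripped.

The model is Goldman–Yang-type on the 61 sense codons: zero rate for
multi-position changes, otherwise \(q_{ij} = \pi_j \kappa^{[ts]}
\omega^{[nonsyn]}\), with F3x4 frequencies estimated jointly from both
sequences (the common default of codon-model software; the frequency model
is a design choice here), Q scaled to one expected substitution per codon.
The likelihood of the codon-pair count matrix is maximized over (t, κ, ω)
by bounded quasi-Newton from three ω starts (0.2, 1, 3), and over (t, κ)
with ω = 1 for the null; 2ΔlnL is referred to χ²(1) even though ω = 1 is
an interior point, matching standard usage. dN and dS are derived from the
fitted flux split between nonsynonymous and synonymous changes with sites
counted from the ω = 1 flux, so dN/dS equals ω̂ exactly. When dS < 1e-6 the
ω estimate is capped at 999 and flagged — the operational form of an
"infinite" ratio at dS = 0. Candidates under divergent selection are pairs
with ω̂ > 1 and BH-adjusted p < 0.05; per-scaffold comparisons use pairs
with ≥ 5 variant sites and a two-sided Mann–Whitney test of each rearranged
scaffold against the pooled rest.

Numerical implementation: the reversible Q is symmetrized in the
\(\pi^{1/2}\) metric, so P(t) = exp(Qt) comes from a symmetric
eigendecomposition — stable and fast enough that the acceptance suite fits
~1,600 pairs in minutes. The test suite pins the likelihood against an
independent brute-force implementation (explicit 61×61 rate matrix, series
matrix exponential) to 1e-6, and the NG86 counting estimator (verified
digit-for-digit against an independent implementation) cross-checks ω̂
where its equal-rate assumptions hold (κ = 1); at κ = 2, NG86's well-known
transition-bias underestimation (~20%) is visible and expected.

# Motifs, TEs, landscape, metabolites

**Motifs.** Four circadian cis-elements are scanned as overlapping exact
matches on the promoter's sense strand (the G-box is its own reverse
complement; a flag enables double-strand scanning): MOE CCACAC, EE
AAAATATC, CBS AAAAATCT, G-box CACGTG. Upstream regions are 2 kb (3 kb for
candidate tables), strand-aware and clipped at scaffold edges; clipped
promoters still use the nominal 2,000-bp denominator in per-kb frequencies
by default (a flag switches to realized lengths). Soft-mask case is
ignored during scanning; N never matches. The DE-vs-background test is a
two-sided Mann–Whitney on per-promoter counts with the background
subsampled without replacement to 5,000. Upstream regions are not trimmed
when they overlap a neighboring gene (no masking rule is imposed).

**TEs.** Gene spans are extended 3 kb on the 5' side only (bedtools-slop
semantics), TEs overlap by ≥ 1 bp under half-open arithmetic (abutting
features never count), only "known" TE annotations and curated genes are
used, and a TE touching several introns of one gene counts once for that
gene region. The presence test is a Yates-corrected chi-square (falling
back to Fisher when an expected cell < 1); the rate test is Mann–Whitney
on raw per-gene counts (not length-normalized). Genes above twice the
genome-wide mean insertion rate are flagged, with ortholog count deltas
for one-to-one pairs.

**Landscape.** Non-overlapping windows from position 0, last partial
window kept; genes assigned by start position; GC computed over A/C/G/T
with N excluded from the denominator; TE content read directly off
soft-masked (lowercase) positions; GC-in-repeats only over masked bases;
genic fractions from merged intervals. Correlations are tie-corrected
Kendall tau-b with Shapiro–Wilk normality p-values reported as the
diagnostic that motivates the rank test; repetitive-to-exonic per-scaffold
ratios are compared with Welch's t.

**Metabolites.** Compound areas are normalized by each sample's main total
ion count (MTIC); the 24-h accumulation statistic is max − min per
accession; species are compared with the exact two-sided Mann–Whitney test
(6 vs 6 accessions); median fold is peak/trough of per-time-point medians.
PCA is on median-imputed, centered, unit-variance-scaled compounds —
scaling is our choice, because compound abundances span orders of
magnitude. Timepoint labels D+1…N+9 map to hours 1, 5, 9, 13, 17, 21 under
a 12-h light cycle.

# The synthetic-data generator

The generator is first-class, tested code and defines the package's test
conditions. One global seed expands into named per-stream child seeds, so
adding a stream never perturbs another; identical seeds give byte-identical
outputs. It emulates: scaffolds with a linear GC gradient (0.42 → 0.34,
roughly the gene-dense-to-repeat-dense range of plant chromosomes); TE
intervals per class (densities of a few per Mb at the default desk scale)
soft-masked into the sequence; genes of 600–1,800 bp with 1–8 exons, 90%
with complete CDS; orthogroups drawn from a configurable category mix
(default 70% 1:1, 10% each F>L, F<L, F=L>1); haplotig inflation as an extra
gene model whose pair sits at half coverage; negative-binomial diel counts
with per-gene sinusoidal log-mean \(b\,e^{A \sin(2\pi(t-\phi)/24)}\); codon
pairs evolved under the same GY-class model the estimator fits (parameter
recovery is then a consistency check; the *likelihood* is checked against
an independent oracle so the circularity is broken); promoters whose
background is rejection-sampled to contain no spurious motif matches before
occurrences are planted at exact Poisson rates; and metabolite tables with
a 3× peak-to-trough malate rhythm in the CAM species versus flat in the C3
species, under lognormal noise (cv 0.2).

What it does *not* emulate — and hence what passing tests do not show about
real data: mappability and GC bias in coverage, shared polymorphism and
alignment error in CDS pairs, linked TE/gene placement, dependence between
expression and sequence evolution, batch effects in counts, or real
promoter base composition. The recovery rates are statements about the
methods' correctness at stated effect sizes, not about field performance.

Problem sizes in the shipped tests and acceptance script (1,000-orthogroup
family-size runs, 10,000-codon estimator checks, 500 neutral pairs of 300
codons, 2,000 null genes, 1,000 promoters, 40-replicate calibrations) were
chosen so each measurement has adequate precision for its band while the
whole suite stays desk-scale.

# Degenerate inputs and edge policies

Empty orthogroups (F = L = 0) are an error; species-unique orthogroups
keep their label but are excluded from enrichment. Identical CDS pairs are
flagged and not tested. Constant expression profiles join clusters by a
zero-distance convention. Zero-margin 2×2 tables return p = 1 with a
degenerate flag. Constant series make tau undefined (reported missing).
Zero-MTIC samples are dropped with a warning. A motif longer than its
promoter is an error; planting collisions are re-drawn so realized counts
equal planted counts exactly.

# Known limitations

* The DE caller tests mean profiles under least squares; strongly
  dispersed low-count genes are better served by count GLMs.
* GO enrichment uses the classic (non-eliminating) Fisher test after
  ancestor propagation; weighted/elim algorithms that decorrelate the DAG
  are out of scope.
* The codon model is single-ratio (one ω per pair): no site or branch-site
  variation.
* Window statistics assume soft-masking is the TE track; hard-masked (N)
  repeats would undercount TE content and GC-in-repeats.
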