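---
title: "Integrating transcriptome, translatome and proteome across the soma-synapse axis"
author: "synaptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating transcriptome, translatome and proteome across the soma-synapse axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptomics)
```

## The scientific problem

Neurons maintain a protein economy that is spatially split: most
transcription happens in the soma, but synapses translate a substantial
fraction of their proteome locally, and many proteins are synthesized
somatically and transported down the axon or dendrite. Comparing a
synaptosome fraction (SYN, resealed nerve terminals obtained by subcellular
fractionation) with the total tissue homogenate (TH) at several ages lets
one ask where each gene product is made, how efficiently it is translated
at the synapse, and whether transcript and protein regulation stay in step
as the tissue ages.

`synaptomics` implements the integration layer of such a study. Its inputs
are three gene-by-sample matrices per study — transcript counts (`rna`),
ribosome-associated transcript counts from a sucrose-cushion pull-down
(`ribo`, the "translatome"), and protein intensities (`protein`) — across
two compartments, three age groups (3 weeks, 5 months, 18 months) and a
few replicates. Everything downstream of read counting and peptide
quantification is in scope; alignment and spectral search are not.

## Data model

Each layer lives in an `OmicsLayer`, a thin `SummarizedExperiment`
subclass whose column data carry the design factors (`compartment`,
`age_group`, numeric `age_days`, `replicate`) and whose row data carry
gene lengths for the count layers. Age enters rank-based statistics only
through its ordering, so the numeric encoding (21, 150, 540 days by
default) is a labelling convenience, not a modelling choice.

## The analysis stages

### Differential abundance (a deliberately simple stand-in)

Counts are normalized by median-of-ratios size factors (the reference is
the per-gene geometric mean over samples, computed on genes detected in
every sample; factors are rescaled to geometric mean 1). Values are then
log2-transformed with a pseudocount of 1 (0 for protein intensities,
which are already strictly positive) and each gene is tested with a Welch
two-sample t-test. No dispersion shrinkage or negative-binomial likelihood
is attempted: every integration statistic downstream consumes only the
fold change and the BH-adjusted p-value, so the differential engine is a
replaceable component, and the simple one keeps the package
dependency-light and its null behaviour easy to audit (see the calibration
tests). The cost is power: with four replicates an unmoderated t-test
rarely survives FDR correction at transcriptome scale, which shapes the
gene-selection rules below.

### Quadrant maps and Fisher's method

For a compartment contrast at one age, the transcript and protein results
are inner-joined per gene. Significance is combined with Fisher's method,

$$X = -2\sum_{i=1}^{k}\ln p_i \sim \chi^2_{2k},$$

applied to the two BH-adjusted p-values. Combining adjusted rather than
raw p-values is statistically unconventional; it is retained deliberately
because it is the convention of the upstream analyses this package
mirrors, and `matchOmics(..., combineOn = "p")` provides the orthodox
alternative. Each matched gene is placed in a quadrant by the sign pair
(transcript fold change, protein fold change), named clockwise from the
upper right: Q1 both enriched, Q2 transcript-enriched/protein-depleted,
Q3 both depleted, Q4 protein-enriched/transcript-depleted. Exact zeros sit
on the boundary. Non-uniformity of the quadrant occupancy is tested by
reducing the four counts to the 2x2 sign-by-sign table and applying the
two-sided Fisher exact test (probability-mass rule, computed from
log-space hypergeometric masses); this sign-association reduction is the
package's reading of "quadrant uniformity", recorded here as an
assumption.

### Translational efficiency

TE is the ratio of replicate-mean RPKMs,
either across compartments (SC\_SYN / SC\_TH, the soma-synapse gradient of
ribosome association) or within one compartment (SC / input, classic
translational efficiency up to the use of whole ribosome-associated
transcripts instead of footprints). One TE per gene is the default; a
per-replicate matrix is available behind `perReplicate = TRUE`. Density
comparisons between gene classes are made on log2 TE — ratios belong on a
symmetric scale — with Wilcoxon or Kruskal-Wallis tests and a
Silverman-bandwidth Gaussian KDE for display.

### Decoupling

The per-gene decoupling score over an age contrast is

$$D = \Delta^{prot}_{\log_2} - \Delta^{rna}_{\log_2},$$

the difference of protein and transcript log2 fold changes. A literal
ratio of the signed fold changes would flip sign whenever both changes
are negative; the log-scale difference is the form under which "positive
means the protein increases more (or decreases less) than the transcript
predicts" holds in all four sign combinations. Decoupling scores feed the
set-level test below, and their correlation with TE changes connects
protein-level decoupling to translational regulation.

Sample-level coupling is the Spearman correlation between transcript RPKM
and protein intensity across genes, computed per (compartment, age,
replicate). Replicate *k* of the RNA layer is paired with replicate *k* of
the protein layer by default — the pairing is not dictated by the data
and an all-pairs variant (`pairing = "all"`) is provided. The resulting
correlations are compared across design cells with a balanced two-way
fixed-effects ANOVA.

### Compartment-coupling trajectory

For an age transition, the per-gene fold changes computed separately in
TH and SYN are correlated (Spearman) over a set of regulated genes. The
selection rule is the product of an explicit design decision. The natural
rule — genes FDR-significant in either compartment — selects almost
nothing under the unmoderated t-test at four replicates; a union of
nominally significant genes instead admits a large contingent of genes
selected by their own noise, whose fold changes are by construction
axis-aligned and dilute the correlation toward zero. The package
therefore requires *concordant nominal evidence*: a gene is kept when its
contrast p-value is below 0.2 in **both** compartments (joint null rate
about 4%) and its normalized base mean is at least 50 in both contrasts
(poorly measured genes carry fold-change noise of over half a log2 unit
and attenuate any correlation). This is the stringent "intersection"
flavour of selection adapted to the power of the differential stand-in.
Both thresholds are plain arguments of `couplingTrajectory()`.

### Gene-set statistics

Three set-level tools operate on per-gene statistics:

* `gageTest()` — a Welch two-sample t-test of a set's scores against the
  background. The background is the universe *minus* the set by default,
  which keeps the two samples disjoint and the test well-defined;
  `background = "universe"` reproduces the whole-universe convention.
  Note this is the set-vs-background *description* of the GAGE
  procedure, not a re-implementation of the `gage` package's internal
  one-on-one sample contrasts.
* `oraTest()` — hypergeometric overrepresentation of a hit list, with
  fold enrichment.
* `overlapComparison()` — are two unique/shared decompositions
  different? (Fisher exact on the 2x2.)

Gene sets come from GMT files; sets are intersected with the analysis
universe and dropped below 5 members, the conventional floor for set
statistics. BH adjustment runs across all tested sets and output rows are
ordered by (p, set name) so results are byte-reproducible.

## The synthetic study

`simulateStudy()` generates the whole design — 2000 genes, 2 compartments
x 3 ages x 3 layers x 4 replicates — with programmed structure and
returns the ground truth beside the data, so every stage above can be
validated end to end without external downloads. Its choices:

* **Counts** are negative binomial with dispersion $\phi(\mu) = 0.1 +
  1/\mu$ (a 10% biological CV floor plus shot noise), baseline log2 means
  Normal(5, 2), and per-sample depth factors $2^{U(-0.5, 0.5)}$ — library
  sizes spread at most two-fold, enough to exercise normalization without
  degeneracy. **Protein intensities** are log-normal (per-sample log2
  noise 0.5) with baseline tied to the transcript baseline through a
  coupling slope of 0.8, and only the top 60% of genes by realized mean
  intensity are detected at all: partial proteome coverage is missingness,
  not zeros.
* **Gene classes** (synaptic 15%, ribosomal 5%, respiratory 5%, vesicle
  5%, nuclear 10%, background 60%) receive +-1 log2 compartment effects
  whose sign pairs place them in the four quadrants: synaptic in Q1,
  ribosomal/respiratory in Q2 (transcript in SYN, protein in TH —
  translational repression), nuclear in Q3, vesicle in Q4 (protein
  transported to the synapse).
* **Development is coupled, aging decoupled.** 3w-to-5m effects are drawn
  once per affected gene (30% of genes, SD 0.5 log2) and applied to both
  compartments; 5m-to-18m effects are drawn independently per compartment
  (same fraction and SD — chosen symmetric with development, as nothing
  in the emulated design distinguishes the two magnitudes) except for the
  programmed ribosomal/respiratory pattern: transcripts up (+0.5) and
  proteins down (-0.75) in TH, transcripts down (-0.75) and proteins up
  (+0.75) in SYN.
* **Translational repression with release.** Ribosomal and respiratory
  genes carry a -1.5 log2 offset on their SYN ribosome-associated
  abundance at 3w and 5m; the offset is released at 18m, so the old-age
  protein gain of these classes coincides with a translational-efficiency
  gain — positive decoupling correlating with rising TE.

What the generator does *not* emulate: ortholog/ID ambiguity between
protein groups and transcripts, peptide-level missingness structure,
batch effects, junction-level splicing, and any age-progressive noise
inflation. One visible consequence of the last point: sample-level
RNA-protein coupling declines with age cleanly in TH (driven by the
independent aging effects), while in SYN the programmed
ribosomal/respiratory pattern moves those genes back toward the diagonal
at 18m and partly offsets the decline. Passing recovery tests demonstrate
that the pipeline detects the programmed structure at realistic noise;
they do not certify performance on real data with the artefacts above.

## Numerical choices and degenerate inputs

* Welch tests follow the zero-statistic convention: both groups constant
  and equal gives t = 0, p = 1; constant but different gives p = 0.
* The two-sided Fisher exact p sums hypergeometric masses no larger than
  the observed one, with a $1 + 10^{-7}$ relative tolerance against
  rounding ties, evaluated in log space.
* Spearman p-values use the large-sample t approximation; |rho| = 1
  returns p = 0.
* Genes with a zero denominator mean are dropped from TE (and counted);
  constant genes yield NA age correlations (and are counted); duplicate
  gene IDs collapse on input, by sum for counts and by max for
  intensities, because counts are additive and intensities are not.
* The two-way ANOVA flags zero-residual fits and reports p = 0 / p = 1 by
  the sign of each term's sum of squares rather than returning NaN F
  ratios.

## Problem sizes

The test-suite and the reproduction script run the full synthetic
pipeline at its default size (2000 genes, 4 replicates, ~1.4 million
simulated counts plus 28&thinsp;800 protein intensities), the null
calibration at 2000 genes with 100 permutations of 50 gene sets, and the
exact-test oracle sweep over all 135&thinsp;751 contingency tables with
total at most 40 — sizes at which every statistical property asserted is
tight and the whole run completes in well under a minute.

## A worked pass

```{r worked, eval = FALSE}
study <- simulateStudy(simParams(seed = 1))
rna <- studyLayer(study, "rna")
prot <- studyLayer(study, "protein")

qm <- quadrantMap(rna, prot, ageGroup = "5m")
qm$quadrant_counts
qm$association$p

te <- translationalEfficiency(studyLayer(study, "ribo"))
da <- decouplingAnalysis(rna, prot, "SYN", "5m", "18m")
couplingTrajectory(rna, "3w", "5m")$rho
couplingTrajectory(rna, "5m", "18m")$rho
```

## Known limitations

The differential stand-in is underpowered relative to
dispersion-moderated NB models, and the selection rules above compensate
for that; on real data a practitioner would substitute DESeq2 or limma
fold changes and adjusted p-values — `matchOmics()` and everything
downstream only require `gene_id`, `log2fc`, `p`, `padj` columns. TE is a
ratio of means and inherits the instability of small denominators; the
expression filter and the dropped-gene count are the guard rails. The
sign-association reduction of quadrant uniformity and the
replicate-matched coupling pairing are documented assumptions, each with
an alternative exposed as an argument.
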