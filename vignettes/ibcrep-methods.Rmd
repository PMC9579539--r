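---
title: "Models and methods behind ibcrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ibcrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`ibcrep` implements the downstream analysis of a multiplexed single-cell
study of high-affinity insulin-reactive B cells (IBCs) in a
diabetes-prone mouse model: donor demultiplexing from hashtag-oligo
counts, immunoglobulin kappa light-chain clonotype and CDR3 analysis
with a strain polymorphism/charge comparison, cluster-marker detection
with z-score projection onto a reference B-cell atlas, and insulin
binding quantification (ELISA titration AUC and 1:1 Langmuir SPR
kinetics).  Because the original sequencing data cannot be recomputed at
desk scale, every pipeline input has a synthetic generator whose
defaults encode the study's stated design, and all validation is
recovery of known ground truth from those generators.

## The synthetic world

### Kappa repertoire

The generator draws one productive kappa contig per cell from a
multinomial over clonotypes.  Its default table fixes the five
predominant light chains at their reported frequencies — Vκ4-74/Jκ5 with
leucine at CDR3 position 97 (35.3%), the same rearrangement with serine
at 97 (28.8%), Vκ4-74/Jκ2 (22.1%), Vκ4-57/Jκ5 (7.4%) and Vκ4-57/Jκ2
(3.2%) — and spreads the remaining 3.2% over 20 rare V/J pairs at 0.16%
each, i.e. below the 0.2% threshold under which rearrangements are
binned as "others".  Four rare pairs carry Jκ5, putting the Jκ5
marginal at 72.14%.  The Vκ4-74 marginal is 86.52% rather than the
reported 87.9%: mouse kappa has only four functional J genes, so once
Vκ4-74/Jκ5, /Jκ2, /Jκ1 and /Jκ4 are spoken for, no additional Vκ4-74
mass can be added without some pair crossing the 0.2% binning
threshold.  The 1.4-point shortfall is well inside the ±5-point
recovery tolerance used throughout.

A contig is the germline V segment, one junction codon (CDR3 position
97), and the germline J segment.  Junctional diversity is reduced to
the two alternative codons at the V–J joint (leucine `CTG` vs serine
`AGC`); this reproduces the observed L/S dimorphism at position 97
without modelling N-nucleotide addition, which is out of scope.  The
default per-base mutation rate is 0, matching the unmutated repertoire
observed; per-mouse cell counts default to 2081/1947/63, and a 0.12%
donor-unassigned fraction adds ~5 cells so that the VDJ total (4,096)
and the hashtag-assigned total (4,091) can both be reproduced — the
study reports both numbers without reconciling them, and so do we.

One source inconsistency is deliberately left visible: the serine
junction variant is once labelled "P" in the source material.  The
generator labels it `"S"` (it is serine), and the label is
configurable.

### Germline reference

The bundled V/J reference is **synthetic**: 96 random sense codons per V
segment (fixed internal seed, identical in every session), with the
CDR3-proximal codons of Vκ4-74 and Vκ4-57 set by hand so the strain
comparison reproduces the reported residues — Q91/Y92 conserved in both
strains, D93/S94 (NOD) ↔ H93/R94 (B6) in Vκ4-74, H93/D95 (NOD) ↔
S93/Y95 (B6) in Vκ4-57.  Real IMGT sequences are deliberately not
bundled; the reference must not be used to annotate real data.

### Hashtags, expression, atlas

Hashtag counts are negative-binomial: NB(mean 300, size 3) on a cell's
own hashtag, NB(mean 3, size 1) elsewhere — a clean cell-hashing
experiment with ~100-fold signal:background.  The multiplet fraction
defaults to 0 because the per-mouse totals being emulated are
post-filter *assigned* counts; multiplet injection is opt-in and its
detection behaviour is tested separately.

Expression counts are NB(mean 2, size 2) with three planted clusters at
proportions 2976/2295/875 of 6,146 cells and 52 marker genes (18
marginal-zone, 17 follicular, 17 memory) up-shifted 4-fold in their
cluster.  The synthetic atlas covers seven populations (MZ, FO, memory,
GC, T1–T3) with each population's signature genes elevated 8-fold in
their home row; two panel genes are withheld from the atlas by default
to emulate the imperfect name-based mapping (50 of 52) seen with real
references.  What a green test establishes is therefore *recovery of a
planted structure*, not fidelity to real ImmGen values: the generator
does not model library-size variation, dropout bursts, batch effects,
or correlated gene programs.

### Sensorgrams and ELISA

Sensorgrams obey the 1:1 Langmuir model: association
$R(t) = R_{eq}\,(1 - e^{-(k_a C + k_d)t})$ with
$R_{eq} = R_{max} k_a C/(k_a C + k_d)$, dissociation
$R(t) = R_0\,e^{-k_d (t - t_{assoc})}$.  Defaults follow the emulated
protocol: six insulin concentrations (100 µM down to 32 nM), 1 min
association, 15 min dissociation, plus a 10 s baseline at a 20 RU
offset, 1 RU Gaussian read noise, and 15 RU fluidics spikes in the
first second after each phase boundary.  True parameters default to
$k_a = 10^5\ \mathrm{M^{-1}s^{-1}}$, $k_d = 10^{-3}\ \mathrm{s^{-1}}$
($K_D = 10$ nM, in the range reported for high-affinity anti-insulin
antibodies), $R_{max} = 100$ RU.  ELISA titrations are a saturating
one-site binding curve over a load plus seven 1:1 dilutions.

## Analysis methods and the choices behind them

**CLR normalization.** The hashtag CLR is computed *within each cell*
across hashtags (`log1p` count minus the cell's mean `log1p` count).
An alternative phrasing — centering each hashtag across cells — fails
the method's own contract that a cell with identical counts on every
hashtag has all-zero CLR values; per-cell centering is therefore used.

**Demultiplexing thresholds.** A hashtag is "positive" when its CLR
exceeds mean + k·SD (k = 2) of that hashtag's CLR over *background
cells* — cells whose top hashtag is a different one — floored at 0.  The
mixture of positives and negatives must be excluded from the threshold
estimate: with three donors, about half of all cells are positive for
hashtag 1, and a mean + 2 SD computed over that bimodal mixture
exceeds the positive mode, assigning nothing.  Assignment requires the
top hashtag to be positive *and* lead the runner-up by a margin
(default 1 CLR unit); failing that, two or more positive hashtags make
a multiplet, anything else is unassigned.  A consequence worth knowing:
strongly skewed doublets (one weak signal) are pulled to their dominant
hashtag — balanced doublets are caught, skewed ones are not, and the
tests encode exactly that.

**Germline assignment.** Smith–Waterman local alignment (match +1,
mismatch −1, gap of length L costs 2 + L — the same convention as
`Biostrings::pairwiseAlignment`, which the test suite uses as an
independent oracle) against every V and J segment; ties broken by
reference order and flagged.  Identical contig sequences are aligned
once.  The CDR3 span is derived from the V alignment assuming
substitution-only divergence; indel-containing alignments are refused
rather than silently mis-numbered.

**Clonotype definition and numbering.** A clonotype is the V×J gene
pair, the granularity at which the emulated figures report
frequencies; junction variants are a sub-annotation.  Mean-across-mice
frequencies weight mice equally (matching a mean ± SEM presentation),
which makes the 63-cell mouse 3 the dominant variance source — visible
in all recovery tolerances.  CDR3 residues are numbered from 89 so the
dominant nine-residue CDR3 puts the V–J joint at 97 (a Kabat-style
kappa convention; the emulated analysis never names its scheme).
Internally all coordinates are 0-based half-open; reports are 1-based.

**Clustering.** PCA (10 PCs) + k-means with k chosen by mean silhouette
width over k = 2..6, computed on a deterministic subsample of ≤ 1000
cells for budget; if the best silhouette is below 0.15 the data are
declared unstructured (k = 1).  This replaces the unspecified
graph-based method of the emulated pipeline with a deterministic,
dependency-light, recovery-testable procedure.

**Markers.** One-vs-rest Wilcoxon rank-sum per gene (normal
approximation with tie and continuity corrections, vectorized; verified
against `stats::wilcox.test` to 1e-12), raw p < 0.05 with a |log2 FC|
floor of 0.25, BH-adjusted p reported alongside.  The 0.05 threshold is
retained from the emulated analysis; the test itself is a documented
substitution for the unspecified original.

**Atlas projection.** For each gene, the median expression within each
population is standardized by that gene's mean and SD across *all*
reference populations ($z_{gp} = (m_{gp} - \mu_g)/\sigma_g$); genes with
zero across-population variance are flagged and zeroed.  Each cluster's
enrichment score per population is the mean z over its up-regulated
mapped genes, and the cluster is assigned the argmax population.

**Kinetic fitting.** Global nonlinear least squares with one
(k_a, k_d, R_max) shared across the concentration series, optimized on
the log scale (`nlminb`) from a 3×3 grid of log-spaced starts; standard
errors from the Gauss–Newton Jacobian; $K_D = k_d/k_a$ by definition.
Global fitting is the default because the original software's
configuration is unreported and the shared-parameter fit is the better
conditioned estimator; per-curve mode exists behind a flag, with the
caveat (encoded in a test) that single-concentration fits have reduced
parameter identifiability even when they reproduce their own trace
perfectly.  Preprocessing subtracts the pre-injection baseline,
re-zeroes time at the injection, and drops a 2 s window after each
phase boundary (no spike width is stated in the emulated protocol; 2 s
covers the simulated 1 s spikes with margin).  Mass-transport and
bivalent-analyte models are out of scope.

**ELISA AUC** is the trapezoid over log10(dilution), and group
comparisons are a thin wrapper over `stats::aov` + `TukeyHSD`.

## Numerical conventions and degenerate inputs

* Frequencies sum to 1 per mouse to 1e-9; probability tables are
  validated to the same tolerance.
* The signature matrix satisfies mean 0 / SD 1 per gene exactly (sample
  SD across populations), except flagged zero-variance genes.
* All-zero expression cells are excluded with a message; empty hashtag
  matrices, non-monotone dilution series, non-positive concentrations,
  and frameshift/stop junctions raise typed errors or flags rather
  than propagating silently.
* Every generator is a pure function of (config, seed); the pipeline
  derives each stage's seed from the master seed, and a config run
  twice produces byte-identical summaries.

## Known limitations

The synthetic world is deliberately simple: no N-nucleotide junctional
diversity beyond the two joint codons, no UMI collisions, no read-level
simulation, no real ImmGen values, no instrument drift beyond a
constant baseline.  Green acceptance tests establish that the pipeline
recovers the stated world's parameters at the stated tolerances — they
do not re-establish the emulated study's biological claims.
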