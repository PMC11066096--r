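---
title: "rbpdyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rbpdyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpdyn)
```

# Scope

`rbpdyn` implements the statistics of a dynamic-RBPome analysis: from
peptide-level quantification tables to (a) an RNase-sensitivity RBPome call,
(b) growth-phase dynamics classes built on a phase-by-extraction interaction
model, (c) enrichment and physicochemical comparisons, and (d) iCLIP peak
post-processing. Upstream steps — spectral search, TMT impurity correction,
read alignment, peak calling — are out of scope; the package consumes their
outputs (quantification tables, BED intervals).

# From peptides to proteins

Modified forms of the same peptide sequence are merged by summing
**linear-scale** intensities (values are stored in log2; aggregation
exponentiates, sums over observed entries, re-logs; a cell missing in every
merged row stays missing — zeros would corrupt log-scale statistics).
Peptides are assigned to master proteins by greedy set cover (most
explainable peptides first, ties by accession order, razor rule for shared
peptides), which is deterministic and order-independent; contaminants map to
a sentinel group, with an exemption list for spike-ins kept deliberately
(porcine trypsin, `P00761`).

Protein values per sample come from a robust additive fit
`value = sample_effect + peptide_effect + error` on log2 intensities,
estimated by iteratively reweighted least squares with Huber weights:

* tuning constant `k = 1.345` (95% efficiency under Gaussian errors),
* scale re-estimated each iteration as MAD/0.6745 of the residuals,
* at most 20 iterations, convergence when the largest coefficient change
  falls below `1e-6`,
* peptide effects constrained to mean zero, so sample effects are on the
  scale of an average peptide,
* missing cells simply drop out of the fit; a sample with no observed
  peptide is missing in the output; a single-peptide protein passes through
  unchanged.

Proteins need at least two distinct quantified peptide sequences
(`min_peptides = 2`) except in the RNase assay, where the spike-in is kept
regardless. After summarisation, each sample column is centre-median
normalised (median subtracted; idempotent). Z-scores for heatmaps use the
sample standard deviation (n − 1) within each extraction type separately;
constant rows are zeroed with a warning rather than erroring, since they
carry no profile information.

# Variance moderation

Sample variances `s²_g` with `d_g` residual degrees of freedom are shrunk
towards a prior estimated by the moment method on log variances
(`e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`). The prior degrees of freedom
`d0` solve `ψ'(d0/2) = mean[(e − ē)² n/(n−1) − ψ'(d/2)]`, inverted by
monotone bisection to `1e-8`; when the right-hand side is non-positive there
is no excess dispersion and `d0 = ∞`, with the prior level then calibrated
by the arithmetic mean of `s²` (the unbiased estimate of a fixed variance —
`exp(ē)` would be biased low by `exp(ψ(d/2) − log(d/2))`). Variances of
exactly zero are floored at `1e-12` before taking logs.

For the RNase assay the prior level is a function of peptide count: a
lowess trend (span 0.75) of `e` on log2(peptide count), evaluated per
protein, so the moderation reflects that high-count proteins are measured
more precisely. With fewer than five testable proteins, or a constant
covariate, the trend is skipped for a global prior. Moderated t-statistics
use `d0 + d` degrees of freedom (standard normal when `d0 = ∞`).

A note on the `d0` estimator: its sampling distribution has a heavy right
tail (as the moment nears zero the inversion diverges), so when summarising
recovery across replicate simulations the package's own checks use the
median across replicates for `d0` and the mean for `s0²`.

# RNase-sensitivity RBPome

Both conditions are spike-in normalised (subtract the spike's log2 value per
sample; the spike row becomes exactly zero and the operation is idempotent).
Ratios are formed per treated/untreated pair as a difference of log2 values;
proteins observed in only one condition are excluded. The per-protein mean
ratio feeds the moderated t-test (the mean is what the t-statistic models;
the median ratio is reported alongside). Calls at BH-adjusted p < 0.01:
negative ratio → RBP (depleted), positive → enriched, fewer than two
observations in either condition → excluded. The default RBPome is the
depleted set; `rbpSet(..., include_enriched = TRUE)` widens it.

# Growth-phase dynamics

Phases are categorical. The per-extraction model `abundance ~ phase` and the
joint model `abundance ~ phase + type + phase:type` are one-way/two-way
layouts, so OLS estimates are cell means and contrasts are differences of
cell means with unit-variance standard errors from the cell counts; the
residual variance pools within-cell sums of squares. The interaction
contrast for phases a→b is `(OOPS_b − OOPS_a) − (total_b − total_a)`; it is
invariant to protein-specific constants and to any phase profile common to
both extractions. A protein with an empty phase-by-type cell is untestable
(NA) rather than silently dropped.

Moderation and BH adjustment are applied **within each coefficient family**
(total phase effect, OOPS phase effect, interaction) — each family has its
own null behaviour and variance scale. Classification at `alpha = 0.01`:

* class iii — interaction significant: RNA binding changes independently of
  abundance;
* class ii — otherwise, OOPS phase effect significant: binding tracks
  abundance. The OOPS effect (not the total) is tested because OOPS is the
  RNA-binding readout; passing the total family's adjusted p-values to
  `classifyDynamics()` switches the convention;
* class i — neither.

The hierarchy iii > ii > i makes the partition unambiguous. Quadrants use
the signs of the stationary-vs-exponential fold changes in total (`dT`) and
OOPS (`dO`): Q1 both up, Q3 both down, Q2 total down/OOPS up, Q4 the
reverse; exact zeros fall in no quadrant. The Q2/Q4 orientation is a fixed
convention — analyses that matter should use the orientation-invariant
unions Q1+Q3 (concordant) vs Q2+Q4 (discordant). Transition sign patterns
(`profilePatterns`) encode each consecutive phase contrast as `+`, `-`, or
`0` (not significant); groups are the distinct patterns, and naming them is
left to the analyst. Profile clustering uses distance `1 − r` (Pearson,
range [0, 2]) with average linkage; constant rows are excluded with a
warning since their correlation is undefined.

# Enrichment and properties

Fisher enrichment is one-sided (over-representation; the hypergeometric
upper tail) with Bonferroni correction by default — two-sided and BH options
exist. The abundance-aware test replaces the hypergeometric null with
resampled foregrounds drawn without replacement using weights that match the
foreground's abundance distribution over 10 equal-count bins of the
background abundance (quantile breaks collapse ties, so a constant abundance
yields uniform weights and the test converges to the plain hypergeometric
p). P-values use the (x+1)/(n+1) correction and BH adjustment; at least 100
resamples are required, 10000 by default.

GRAVY is the mean Kyte–Doolittle hydropathy; net charge follows
Henderson–Hasselbalch with the Lehninger pKa set including both termini.
Group comparisons first test variance equality with the Brown–Forsythe
(median-centred Levene) test at 0.05, then use the pooled t-test when
variances are compatible and Welch otherwise.

# iCLIP post-processing

Cross-link sites are one base 5′ of the aligned read: 0-based `start − 1` on
the plus strand, and on the minus strand the mirrored convention
(`site = alignment end`, 0-based), configurable since only the plus-strand
rule is universal. Sites before the chromosome start are dropped and
counted. Blacklisting removes peaks overlapping any control peak by ≥ 1 bp,
strand-insensitive (mirroring `bedtools intersect -v` without a strand
flag); replicate intersection keeps anchor peaks reciprocally overlapped by
≥ 10% of **both** intervals in every other replicate, the best (largest)
overlap per replicate serving as the match. Consensus coordinates are the
anchor replicate's peak — the merged interval is not otherwise defined.
Medians of matched scores and sizes use the midpoint convention for even
counts. Targets require log2(median score) > 5 **and** log2(size) > 2,
strictly, as printed thresholds with `>`; non-positive scores are excluded
with a warning. Biotype densities divide summed cross-link counts (assigned
by containment with a configurable priority order; uncovered positions form
an "unannotated" bucket) by the merged genomic space of each biotype; a
presentation remap (e.g. tRNA/rRNA → "intergenic") is applied only at
report time.

# What the simulators emulate — and what they do not

`simulateProteomeExperiment` reproduces the study design: three phases with
4/3/3 replicates per extraction, class fractions allocated deterministically
(`floor(fraction·n)`, remainders in order, so label counts are exactly
testable), baseline log2 abundances N(20, 2), phase effects of ±2 log2
units applied at the stationary phase (both extractions for class ii, OOPS
only for class iii), peptide counts `1 + Poisson(mean − 1)` capped at 30,
peptide offsets N(0, 1), Gaussian noise with SD
`sigma0·(1 + slope/peptide_count)` (defaults 0.25 and 1 — the count-
dependent precision that motivates trended moderation), and 5% completely-
at-random missingness. `simulateRnaseAssay` additionally injects per-sample
global offsets (SD 0.5) so spike-in normalisation has something to remove,
and shares peptide offsets between conditions because the same peptides are
measured in both. `simulateIclip` draws per-position Poisson counts
(background 0.001/bp, signal 0.5/bp inside 20 planted 100-bp targets for CL
replicates; background only in controls) and emits peaks as ≥ 1-count
positions merged across gaps of ≤ 20 bp, kept when the summed count exceeds
5. The 20-bp gap is chosen from the rates: a zero-run that long inside a
signal region has probability ≈ 1e-6 per position, while background events
sit ~1000 bp apart, so targets emerge as single peaks and background
virtually never passes the threshold.

Real data differ in ways the simulators deliberately ignore: missingness is
intensity-dependent (not MCAR), TMT plexes have batch and channel structure,
noise is heavier-tailed than Gaussian, peptide ionisation effects are not
additive, iCLIP cross-linking has sequence bias, and annotations are
imperfect. Passing tests therefore demonstrate correctness of the
statistical machinery under its stated assumptions — not robustness to
every artefact of real instruments.

# Verification

The test suite checks every operation against independent oracles:
closed-form values (BH step-up by hand, hypergeometric tail enumeration,
GRAVY arithmetic), brute-force algorithms (quadratic interval overlap,
literal reciprocal-intersection, UPGMA by explicit enumeration, a separately
coded implementation of the moment equations), reference implementations
(`limma::squeezeVar`, `MASS::rlm`), and parameter recovery on simulated data
with known truth. Calibration checks simulate 20 independent
1000-protein experiments at zero effect: the class-iii rate at 1% FDR stays
at the nominal level and the raw interaction p-values, pooled across
experiments, pass a Kolmogorov–Smirnov uniformity check (pooling matters:
within one experiment the p-values share normalisation and moderation, which
overdisperses a per-experiment KS statistic even though rejection rates are
nominal). Recovery checks use 1000 proteins × 10 experiments (dynamics
classes, ≥ 95% recovered) and 500 proteins × 20 experiments (RNase assay).
These sizes keep the full suite around two minutes on one CPU while leaving
Monte-Carlo error well below the margins tested.

# Known limitations

* No protein-level imputation; missingness propagates to NA contrasts.
* The interaction test needs both extractions observed in at least two
  phases; sparse proteins are reported untestable rather than guessed.
* The abundance-matched resampling null is a documented stand-in for the
  unspecified "modified hypergeometric" construction; its weights are
  estimated from 10 bins and degrade when the foreground is tiny.
* Peaks are consumed, not called: the package post-processes peak-caller
  output (or its simulator's threshold runs) and does not reimplement
  peak calling.
* GO-style term relationships are not modelled; terms are opaque labels.
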