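---
title: "Models and methods behind the translatome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the translatome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translatome)
```

# The experimental design being modelled

The package analyses fraction-resolved gene expression in
*Pichia pastoris* grown under four carbon regimes: excess glucose (D,
the control), excess glycerol (G), methanol feeding (M) and limiting
glucose supplied by slow-release feed beads (X). For each condition,
three RNA pools — total, monosome-bound (80S) and polysome-bound mRNA
— are isolated from sucrose-gradient fractions and hybridized on
two-colour microarrays against one common reference pool, in dye-swap
pairs. Two cell-level and one transcript-level readouts matter:

* the **P:M ratio**, the polysome-region area divided by the 80S
  monosome peak area of the A254 gradient trace — a cellular measure
  of translational activity;
* **transcriptional regulation**, contrasts of total-RNA abundance in
  G, M, X versus the glucose control;
* the **translational state (TS)** of each transcript, its polysome
  abundance normalized to its total abundance, whose change versus the
  control classifies transcripts as translationally enriched or
  depleted.

# The synthetic-data generator

Every stage is testable without external data because the generator
produces complete synthetic experiments with known ground truth. Its
defaults are the study conditions; they are not tuned per analysis.

**Gene catalog.** ORF lengths are log-normal with `meanlog = log(1203)`
and `sdlog` solving a mean of 1444 bp (the annotated genome's median
and mean), truncated to the observed 141–14853 bp and rounded to whole
codons. The right-skewed law reproduces mean > median. Genes are
grouped by the fixed annotation quartile cutoffs (short < 770 bp,
long > 1807 bp). Group-dependent properties mirror the annotation:
5'UTR presence probabilities 0.50/0.10/0.02 (long/medium/short),
target mean SCUO 0.078/0.105/0.198, and a baseline abundance that
falls by 0.6 log2 units per log2 length unit (short genes are more
highly expressed). A coding sequence is emitted per gene by sampling
each synonymous codon family with a "one preferred codon" probability
vector whose normalized entropy matches the gene's bias target.
Finite sequences push the *measured* entropy-based bias above its
target — strongly so for short genes — which the analysis sees exactly
as an annotation pipeline would; only the ordering of group means is
asserted, not the finite-sample values.

**Polysome affinity and mixing.** The condition-level polysome share
is `s_c = pm/(1 + pm)`, the simplest share consistent with P:M being
an area ratio. Each transcript carries a length-linked polysome
affinity (log2 affinity falling 0.17 per log2 length unit, so short
transcripts are relatively polysome-enriched — the pattern observed in
the study's length-group table), and a condition-relative true TS
(1 in the control by construction). The polysome pool is
`total × min(s_c × affinity × TS, 0.99)` and the monosome pool the
remainder, so `total = monosome + polysome` holds *exactly* before
measurement noise; clipping at 0.99 keeps the monosome pool positive
and is reported with a warning.

**Arrays.** The reference channel carries the pooled mean abundance
(the paper does not state the pool's composition; the pooled mean is
an explicit assumption). A per-array log-normal scale factor, a
quadratic intensity-dependent dye bias on the log-ratio (applied with
the dye, so swaps see it with opposite sign relative to the sample),
and log-normal per-channel measurement noise (sdlog 0.10) complete the
model. Replicate biology enters as log-normal noise on the total pool
(sdlog 0.25). There is no background model: the pipeline operates on
raw, background-free intensities throughout.

**Traces.** A gradient trace is a linear baseline drift plus Gaussian
peaks: 40S, 60S, 80S, and five polysome peaks whose areas decay
geometrically (ratio 0.65) and broaden along the gradient, plus white
noise. The polysome area sum divided by the 80S area equals the
requested P:M exactly in the noise-free construction, and the true
areas are returned so the analyser can be scored against them.

Default problem sizes used in the tests and the acceptance script —
catalogs of 1200–5000 genes, 3 replicates, 100-trace P:M panels — were
chosen as the smallest sizes at which the binomial noise on the
recovery rates is comfortably below the asserted margins.

# Profile analysis

The P:M analyser must reproduce what an operator does with ImageJ:
subtract a baseline, delimit peaks, integrate. The steps:

1. **Smoothing** is Savitzky–Golay (cubic, ~2.5 gradient units wide),
   which preserves peak areas far better than a boxcar.
2. **Baseline.** The default estimator is an asymmetric least-squares
   polynomial fit (points above the fit weighted 0.001, at or below
   it 1, iterated), degree 1 by default. A rolling-minimum variant is
   available (`method = "rolling_min"`), but on traces with positive
   drift it mistakes the valleys inside the polysome cluster for
   baseline and can err by several-fold at low P:M, which is why it is
   not the default.
3. **Segmentation.** The first three prominent peaks (topographic
   prominence ≥ 5% of the corrected maximum, ties broken by position)
   are labeled 40S, 60S, 80S; boundaries sit at the local minima
   between them, and the polysome region runs from the minimum after
   the 80S peak to the last recorded position (no pellet modelling).
   Fewer than four prominent peaks is an error naming the count.
4. **Refinement.** Once the peaks are located, the drift is refit as a
   line through the two signal-free anchor windows — the lead-in
   before the 40S peak and the trailing 8% of the gradient. This
   removes the small residual bias of the envelope fit under the
   polysome cluster.
5. **Areas** are trapezoidal integrals of the *unclipped*
   baseline-subtracted residual. Clipping at zero before integration
   would rectify noise into a positive bias of order
   noise × region-width, which is material against a small polysome
   area; integrating the residual lets zero-mean noise cancel. The
   corrected trace object itself is clipped at zero, which is what a
   display or an operator expects. P:M is invariant under rescaling
   of the absorbance, and the 40S/60S peaks are excluded from both
   P and M.

On 100 simulated traces spanning P:M 0.3–4 at default noise the median
relative error is about 1% and the worst case about 10%, with Spearman
correlation > 0.999 to the truth.

# Normalization

The preprocessing order is: MA transform → within-array loess colour
normalization → dye-swap combination → between-array quantile
normalization. M is orientation-corrected at the transform stage so
that positive M always means sample above reference.

The loess step fits a robust local-linear trend of M on A (span 0.3,
three robustifying iterations) per array and subtracts it. Residual
trend QC is evaluated over the central 96% of each array's A range:
at the extreme intensities the fit is extrapolation over a handful of
spots and not a meaningful bias measure. Bias-removal tests use
effect-free simulations deliberately — real transcriptional and
translational effects correlated with abundance create genuine M–A
structure, and on such data "residual trend" conflates dye bias with
biology.

Quantile normalization maps every column to the mean of the sorted
columns (ties averaged; idempotent). Whether the original analysis
quantile-normalized single-channel intensities or log-ratios is not
stated; the package normalizes the combined per-sample log-ratio
matrix by default, which also absorbs condition-level shifts in
polysome occupancy, and exposes `quantile = "none"` for the
alternative. Dye-swap pairs are combined by averaging the two
orientation-corrected M values, which cancels residual dye bias and
halves technical noise variance (verified on null pairs).

PCA QC is a centered `prcomp` of the samples with
variance-explained fractions and a within- versus between-condition
score-distance summary. The variance percentages reported in the
original study's biplots depend on unstated preprocessing of raw
single-channel intensities and are not reproduced as numbers.

# Differential expression and the translational state

Contrasts are differences of per-gene means on the normalized log2
ratios (the common-reference design makes this the natural
parameterization; the original limma design is not stated). The
moderated t shrinks gene-wise variances toward a scaled
inverse-chi-square prior fitted by method of moments on log variances
(trigamma inversion by Newton's method), with `df_prior` added to the
residual degrees of freedom — the empirical-Bayes scheme standard in
microarray analysis, and it matches limma's `eBayes` to a fraction of
a percent on shared data (an independent cross-check in the test
suite, not the implementation). Tests are two-sided; BH adjustment is
applied within each contrast; a gene is called up/down when
|log2FC| ≥ log2(1.5) and adjusted p < 0.05. The ±50% cutoff is
interpreted log-symmetrically, consistent with marginal published
calls at log2FC ≈ 0.6.

The translational state of a transcript is its polysome log2 ratio
minus its total log2 ratio, computed per replicate; replicate noise in
the total pool cancels in this difference. Relative TS versus the
control condition is tested with the same moderated machinery, BH per
contrast, and the same ±50%/α call rule (enriched/depleted). The
monosome fraction is used only by the integrity check, which regresses
log10(total) on log10(monosome + polysome) on the intensity scale:
exact mixing gives R² = 1 and slope 1; at default measurement noise
R² stays above 0.99.

**A ceiling effect worth knowing about.** Under the mixing model a
transcript's polysome share cannot exceed 1. In a condition whose
baseline share is already high (methanol, s ≈ 0.72), a true 2-fold
enrichment saturates at the ceiling and its measured relative TS
compresses toward ~1.4; depletion is unaffected. The TS recovery
experiments therefore quantify enrichment sensitivity in a
low-share design (P:M 0.7 in both conditions), where a 2-fold effect
is physically representable, and the test suite demonstrates the
saturation explicitly in the high-share condition. On real data the
analogous caveat is that enrichment of already heavily polysome-bound
transcripts is bounded by fraction arithmetic.

# Sequence features

SCUO (synonymous codon usage order) is computed from first principles:
for each degenerate amino acid, the normalized entropy deficit of its
synonymous codon usage, averaged with weights equal to the amino
acid's share of degenerate-codon occurrences; Met, Trp and stops are
excluded. Natural logarithms are used — the ratio makes the measure
base-independent. The implementation is vectorized over whole catalogs
and is verified against a brute-force tally oracle.

Length groups use the fixed annotation cutoffs (770/1807 bp, boundary
values medium) by default, with a quantile mode for arbitrary
catalogs. The association battery covers: linear regression of log2
expression intensity on length; Spearman rank association of SCUO with
length plus an exponential-decay least-squares fit (the original
"non-linear regression" names no model, so both a rank-based and a
parametric form are reported); linear regression of mean log TS on
length; Fisher exact (long vs short) and chi-square (all groups) tests
of 5'UTR presence by length group; and Shapiro–Wilk per group followed
by pairwise Wilcoxon rank tests (normality generally fails, hence the
rank tests). Expression intensity for between-gene comparisons is
taken from the sample-channel array intensities — the normalized
log-ratios are per-gene relative to the reference and carry no
between-gene information.

# The feed-bead growth model

A feed bead releases glucose cumulatively as S(t) = 1.63·t^0.74 mg per
disc. At harvest (t = 16 h, 9 beads) the instantaneous rate
n·a·b·t^(b−1) gives 5.28 mg/h and the final-hour average
n·(S(16) − S(15)) gives 5.32 mg/h; both are within 1% of each other
and the published figure, and the differentiation convention used in
the original work is not stated, so both modes are provided
(instantaneous default). The quasi-steady growth rate is
μ = feed·Y_X/S / (X·V) with Y_X/S = 0.37 g/g, X = 3.3 g DCW/L,
V = 40 mL: μ = 0.0149 ≈ 0.015 h⁻¹. One-at-a-time ±35% perturbation of
feed, yield and biomass gives extremes of 0.0096 (≈ 0.010) and
0.0228 h⁻¹; the published upper bound of 0.022 is not exactly
reproduced by any single perturbation (biomass × 0.65 gives 0.023),
so the package reports its own computed bound.

# Pipeline, determinism and degenerate inputs

`run_pipeline()` chains simulate → profiles → normalize → de → ts →
features → growth → report over one output directory; stages
communicate only through documented TSV/FASTA files, a manifest
records md5 sums, parameters and the seed per stage, and rerunning
with the same configuration and seed reproduces outputs bit for bit.
All randomness derives from a single master seed through fixed child
streams. Degenerate inputs fail loudly and specifically: traces with
fewer than four prominent peaks, non-monotone positions, non-positive
intensities (named gene and array), unpaired dye-swap samples (named),
unknown controls, fold-change cutoffs ≤ 1, empty length groups, and
p-values outside (0, 1].

# What passing tests do and do not show

The generator emulates the design factors the analysis must be robust
to — dye bias, array scale, dye swaps, fraction mixing, length-linked
expression, affinity and codon bias — with smooth parametric forms and
log-normal noise. Real arrays add spatial artifacts, probe-specific
effects, saturation and background structure that are deliberately out
of scope (the original data were not background-corrected, and probe
design is a platform property). Recovery rates measured here therefore
characterize the statistical machinery under the stated model, not
platform-specific behaviour. Re-analysis of the original raw arrays
(supplementary files without a public accession) is supported by the
same readers but is not part of the automated suite; exact agreement
with the published regulated-gene counts is not expected because the
original limma design details are unstated.
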