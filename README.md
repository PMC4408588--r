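# translatome

Polysome-profiling translatome analysis for carbon-limited yeast.

`translatome` is an R package for fraction-resolved (total / monosome
/ polysome) two-colour microarray experiments of the kind used to
study translational regulation in *Pichia pastoris* across carbon
regimes — excess glucose (D, control), excess glycerol (G), methanol
(M) and feed-bead-limited glucose (X). It is aimed at groups doing
polysome fractionation with array (or array-like) readouts who need
the whole chain from gradient trace to per-transcript calls in one
tested toolbox.

The core quantities:

* **P:M ratio** — polysome-region area over 80S monosome peak area of
  the A254 gradient trace, a cell-level measure of translational
  activity: baseline correction, peak labeling (40S, 60S, 80S,
  polysomes) and trapezoidal integration.
* **Transcriptional contrasts** — per-gene moderated t-tests of
  normalized log2 ratios vs the control, empirical-Bayes variance
  shrinkage, Benjamini–Hochberg FDR, and calls at
  |log2FC| ≥ log2(1.5) with adjusted p < 0.05.
* **Translational state (TS)** — per transcript,
  `log2(polysome) − log2(total)`; its change vs the control classifies
  transcripts as translationally enriched or depleted under the same
  ±50%/FDR rule. A fraction-integrity check regresses log10(total) on
  log10(monosome + polysome).
* **ORF-feature associations** — length groups (770/1807 bp cutoffs),
  SCUO codon-bias (entropy-based, 0–1), 5'UTR frequency, and the
  regression / Fisher / chi-square / Shapiro–Wilk / Wilcoxon battery
  linking them.
* **Feed-bead growth model** — glucose release S(t) = 1.63·t^0.74 mg
  per disc, the derived quasi-steady growth rate
  μ = feed·Y_X/S/(X·V), and one-at-a-time sensitivity bounds.

A synthetic-data generator (gene catalog with calibrated length / UTR
/ codon-bias / abundance structure, ground-truth effects, fraction
mixing with exact total = monosome + polysome conservation, dye-swap
arrays with injected dye bias, gradient traces with known peak areas)
makes every stage testable without external data. See the methods
vignette (`vignettes/translatome-methods.Rmd`) for the models and the
design decisions.

## Worked example

```r
library(translatome)

# simulate a four-condition experiment with known ground truth
catalog <- generate_gene_catalog(1500, seed = 1)
truth   <- generate_ground_truth(catalog, seed = 1)
abund   <- simulate_fraction_abundances(truth, catalog, seed = 1)
sheet   <- make_sample_sheet()
arrays  <- simulate_arrays(abund, sheet, seed = 1)

# gradient trace -> P:M
sim <- simulate_profile_trace(2.5, seed = 7)
analyze_trace(sim)
#> P:M ratio: 2.478
#> areas: 40S=0.2563, 60S=0.3484, monosome=0.9952, polysome=2.466

# preprocess, contrast, classify
expr <- normalize_arrays(arrays)
de   <- fit_condition_contrasts(expr, control = "D")
table(de$contrast, de$call)
#>        down   ns   up
#>   G-D    33 1440   27
#>   M-D   111 1289  100
#>   X-D   359  782  359

rel <- relative_ts(compute_translational_state(expr), control = "D")
fraction_integrity(arrays, "X")
#> Fraction integrity: R^2 = 0.998, slope = 1.000 (n = 1500 genes)

# growth under feed beads: ~5.3 mg/h at harvest, mu ~ 0.015 1/h
release_rate(16, 9)            #> 5.279474
growth_rate(5.32)              #> 0.01491212
sensitivity_range()$mu_min     #> 0.009619041

# or run everything as a pipeline with a manifest and report
res <- run_pipeline(default_run_config(seed = 1, outdir = "run1"))
```

The P:M estimate reproduces the simulated truth to ~1% (median over
the 0.3–4 range); transcriptional spikes of |log2FC| = 1.5 are
detected with ~0.9 sensitivity at 3 replicates; the integrity
regression returns R² ≈ 1 because the simulator mixes fractions
exactly and only measurement noise intervenes.

A thin command-line wrapper for the pipeline ships in
`inst/cli/translatome.R`.

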