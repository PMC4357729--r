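---
title: "Scoring AP-MS interactomes by spectral counting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring AP-MS interactomes by spectral counting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsde)
```

## The analysis problem

An affinity-purification mass-spectrometry (AP-MS) screen pulls down a bait
protein and identifies the co-purifying proteins by LC-MS/MS, quantified
here by label-free spectral counting: the number of MS/MS spectra assigned
to peptides of a protein, a semi-quantitative proxy for its abundance.
`apmsde` covers the computational half of such a screen in neural stem
cells (NSCs) profiled in two states — proliferating (maintenance medium)
and differentiating — against a negative-control purification, with
cytoplasmic and nuclear fractions per NSC sample:

1. **Fraction merging and identification summary.** Per (protein, sample),
   fraction counts are summed into a whole-sample count; triples absent
   from the table count as zero, the natural convention for sparse AP-MS
   identification lists.
2. **Enrichment over the negative control.** A one-sided exact count test
   per protein asks whether the NSC pull-downs exceed the control rate.
3. **Differential abundance between states.** An intensity-binned robust
   z-test on the log2 count ratio calls proteins more abundant in
   differentiation or in maintenance.
4. **GO over-representation.** One-sided Fisher tests with
   Benjamini–Hochberg (BH) control over the tested terms.
5. **Network context.** Physical-interaction filtering of a PPI edge list
   and extraction of the first-neighbor subnetwork around the enriched
   set.

A synthetic-data generator with known ground truth accompanies the
pipeline so every stage is verifiable without access to raw screen data.

## Enrichment against a sparse negative control

Let `c` be the control count and `s_d`, `s_p` the whole-sample NSC counts
of one protein. Under a Poisson model with equal per-sample rates, the
control count conditional on the total `t = c + s_d + s_p` is
Binomial(`t`, 1/3) — one control sample against two NSC samples. The
default test therefore reports

> p = P(X <= c), X ~ Binomial(c + s_d + s_p, 1/3),

the uniformly-most-powerful-unbiased exact comparison of Poisson rates. It
uses both NSC replicates without rounding and needs no pseudocount: an
all-zero protein gives p = 1. A protein is *enriched* when `p < 0.1`
(strict), and only enriched proteins observed in **both** NSC samples move
on to the differential stage (a fold change needs two positive counts).

A literal "Poisson tail" variant is kept as a configurable method
(`enrichment_config(method = "poisson-tail")`): `p = P(Y >= round(m))` for
`Y ~ Poisson(max(c, pseudocount))` with `m` the mean NSC count, half-up
rounding, and a 0.5 pseudocount because a control rate of exactly zero
would make any observation infinitely significant. The conditional
binomial is the default because it is exact, needs no such guard, and
treats the two NSC samples as what they are — two exposures of the same
rate. No library-size normalization happens before this test: exact count
tests need raw integers, and depth differences are handled downstream.

## The intensity-binned robust z-test

Spectral-count ratio noise shrinks with abundance: for Poisson counts the
SD of the log2 ratio scales roughly like `sqrt(2/lambda)/ln 2`. A single
global null scale would therefore over-call faint proteins and under-call
abundant ones. The differential stage:

1. Optionally rescales each sample's counts so both totals equal their
   mean (`normalize_depth = TRUE`), compensating unequal overall depth.
2. Computes per protein the intensity `I = log2((n_d + n_p)/2)` and the
   ratio `r = log2(n_d/n_p)` from the normalized counts. "Intensity" is
   defined as the log2 *mean* normalized count across the two samples — a
   symmetric choice so that binning does not depend on the direction of
   change.
3. Ranks proteins by intensity (ties broken by protein id, so results are
   reproducible under row reordering) and cuts them into consecutive
   equal-occupancy bins of about 150 proteins; a trailing remainder under
   50 is merged into the last bin. Equal occupancy (rather than equal
   intensity width) keeps the scale estimate equally stable in every bin;
   150 gives roughly 8–13 bins on screens of one to two thousand
   quantifiable proteins, enough resolution for a smoothly varying noise
   scale while keeping ~150 points per scale estimate.
4. Estimates each bin's location `mu_b` and scale `sigma_b` after removing
   the `floor(0.025 n)` smallest and largest ratios (2.5% per side). A
   trimmed SD is biased low under normality; it is divided by the
   truncated-normal consistency constant
   `sqrt(1 - 2 a phi(a)/(2 Phi(a) - 1))` with `a = qnorm(0.975)`
   (about 0.8711), so that nominal error rates are honest. The correction
   can be switched off to mimic a naive trimmed SD.
5. Standardizes **every** member of the bin — including the trimmed ones —
   as `z = (r - mu_b)/sigma_b`; the within-bin standardization is simply
   extended linearly beyond the trimmed range. Two-sided p-values
   `2(1 - Phi(|z|))` are the default because both directions of change are
   reported against one threshold.
6. Calls a protein differential when `p < 0.1` **and** `|r| > 0.5`, both
   strict. The fold-change filter can only remove calls, never add them.

Degenerate bins (zero trimmed spread) fall back to the pooled corrected
trimmed SD over all ratios; if that is also zero the affected proteins get
p = 1 with a warning rather than an error — a flat screen should report
nothing, not crash.

### Known limitation: contamination of the bin scale

The 2.5% trim protects the scale estimate against a *few* outliers, not
against a substantial fraction of genuinely changed proteins. When ~17% of
proteins carry true effects of 0.8–2.5 log2 units, the trimmed bins retain
most of them, `sigma_b` inflates to roughly 0.55–0.75 even for noise-free
counts, and the p-value filter then effectively demands
`|r| > 1.645 * sigma_b ≈ 1.0–1.2`. Effects near the lower end of that
range are systematically missed: sensitivity plateaus around 0.6–0.8
depending on the counting noise, while the FDR stays low (the procedure is
conservative, not anti-conservative, under contamination). This is a
property of the published procedure itself — a fixed small trim cannot
adapt to heavy two-sided contamination — and users screening for moderate
effects should read non-calls accordingly. The test suite measures this
honestly on the generator's defaults rather than hiding it.

## GO over-representation

For the test set (by default the up-in-differentiation call set) against
the background of **all** proteins identified in any sample, each GO term
is tested with the one-sided hypergeometric upper tail
`P(X >= k)` — Fisher's exact test for over-representation. Only terms
annotating at least one test-set protein and at least two background
proteins are tested, so vacuous terms do not inflate the BH denominator;
the BH adjustment runs across exactly the tested terms and significance is
`q < 0.1`, strict. Annotations are used as given — no propagation up the
GO graph is attempted, since nothing in the pipeline depends on the
ontology's structure and propagated and unpropagated annotation files are
both in common use.

## PPI subnetworks

Curated interaction exports mix physical and functional edges; the types
"transcription regulation" and "transport" are discarded
(case-insensitively), and unknown labels are kept — only the named
exclusion list removes edges. The first-neighbor subnetwork around the
enriched set is the subgraph *induced* by the seeds present in the graph
plus all nodes adjacent to a seed: neighbor–neighbor edges are retained,
which is the standard reading of a direct-interaction neighborhood and
keeps the displayed network faithful to the underlying adjacency. Seeds
absent from the edge list are reported separately rather than silently
dropped. Edge lists are undirected and canonicalized by sorted endpoint
pair; SIF lines containing a tab are split on tabs (so type labels may
contain spaces), otherwise on spaces.

## Small assay computations

Two defined readout computations round out the toolkit:
`pearson_colocalization()` classifies a cell as showing colocalization of
two fluorescence channels when the Pearson coefficient of paired per-pixel
intensities is at least 0.3 (inclusive); constant channels yield an
explicit NA, never a call. `normalize_reporter()` forms the miRNA-sensor
activity `mean(WT wells)/mean(mutant wells)`, with optional rescaling to a
reference condition; replicate wells are aggregated by the arithmetic
mean. Image segmentation and background handling are out of scope — the
inputs are already-paired intensity vectors.

## The synthetic generator

`sim_config()` freezes the study conditions the generator emulates:

* 2641 proteins, of which a fraction 29/2641 is genuinely present in the
  negative control at rate 4 — a sparse control, matching a clean mock
  purification;
* NSC whole-sample rates log-uniform on [2, 200] spectral counts, split
  0.6/0.4 over cytoplasmic and nuclear fractions;
* 10% of proteins truly up in differentiation and 7% up in maintenance,
  with |log2 effect| uniform on [0.8, 2.5];
* extra-Poisson ratio noise with SD `0.1 + 0.5/sqrt(lambda)` on the log2
  scale — heteroscedastic by construction, because that is the regime in
  which intensity binning earns its keep (the test suite compares binned
  against unbinned calibration on exactly this structure);
* 200 GO terms at background prevalence 1–5%, ten of them annotating
  true-up proteins at 10-fold odds;
* an Erdős–Rényi-like PPI layer at mean degree 4 with a 20% share of
  non-physical edge types and a guaranteed physical edge per true-up
  protein.

Counts are Poisson draws per fraction; all stages are deterministic given
one integer seed, with per-stage derived streams so regenerating one
artifact never perturbs another. What the generator does **not** emulate:
peptide-level identification noise, shared-peptide inference, correlated
contaminant batches, or annotation bias toward well-studied proteins.
Passing tests on synthetic data therefore demonstrate the statistical
machinery under its stated model, not robustness to everything real
screens do.

## Numerical and interface choices

* Strict inequalities everywhere a threshold is stated ("below 0.1",
  "above 0.5"); an exactly-threshold value is not a call. The
  colocalization threshold is the one inclusive comparison (>= 0.3).
* Counts are validated as non-negative integers at parse time with the
  offending line number; duplicated (protein, sample, fraction) triples
  are an error, not a silent sum.
* The count table is long (tidy), so fractions and missingness are
  explicit; pre-merged tables are accepted via
  `read_count_table(merged = TRUE)` since either form circulates.
* Protein identifiers are opaque strings; no cross-referencing or mapping
  is attempted.
* Output tables are plain TSV plus a manifest echoing the configuration,
  package version and row counts. The manifest deliberately carries no
  timestamp: reruns on identical inputs are byte-identical, which makes
  "did anything change?" a file comparison.
* Test and verification problem sizes — a 2816-point count grid for the
  exact-test oracle, 5000 proteins for null calibration, 2000 for
  ground-truth recovery, 2641 for the screen-scale run — were chosen to
  make Monte-Carlo error small relative to the tolerances being checked
  while keeping a full run in the low minutes on one core.

## Using the pipeline

```{r example, eval = FALSE}
d <- generate_dataset(sim_config(), seed = 1)
res <- run_pipeline(d$counts, d$annotations, d$edges, out_dir = "results")
res
```

Each stage is also exported on its own (`sum_fractions()`,
`enrichment_filter()`, `differential_test()`, `go_enrichment()`,
`filter_physical_edges()`, `first_neighbor_subnetwork()`), and a thin
command-line wrapper with `run`, `simulate` and `summary` subcommands
ships in `inst/scripts/apmsde-cli.R`.
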