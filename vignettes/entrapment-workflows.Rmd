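---
title: "Entrapment fidelity metrics and matching-enhancer quantification workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entrapment fidelity metrics and matching-enhancer quantification workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diametrics)
```

## The problem this package addresses

Data-independent acquisition (DIA) software identifies peptides in two
passes: a first pass builds an internal spectral library from the runs
being co-analyzed, and a second pass ("match-between-runs", MBR)
re-extracts signals for library entries in every run. Co-analyzing
low-input runs with a few deliberately higher-input runs — *matching
enhancers* (MEs) — enlarges that library and can substantially deepen
the proteome coverage of samples down to single-cell inputs. The price
is a new error mode: an identity present only in the library can be
falsely transferred into a run where it is not actually present.

Two-proteome entrapment experiments make that error measurable. A
foreign proteome (*E. coli*) is spiked into human samples at known
weight fractions; any *E. coli* identification in a pure human run is a
known error. `diametrics` implements the post-processing around such
experiments: the fidelity statistics, the filtering rules, the
ME-exclusion + re-normalization quantification workflow, single-cell
differential expression and co-variation analysis, and a synthetic
report generator with complete ground truth so that every stage can be
validated without raw mass-spectrometry data.

## Fidelity statistics

Counting distinct identified units (precursors or protein groups) per
replicate, split by species and with shared-species records excluded:

* **False-positive rate (FPR)** — the entrapment fraction of all
  identifications in a non-spiked replicate,
  $\mathrm{FPR} = \mathrm{IDs}_{E.coli} / \mathrm{IDs}_{Total}$.
* **False-transfer rate (FTR)** — the entrapment fraction of the
  identifications *gained by matching*, computed on count differences
  between the matched and individual analysis of the same replicate:
  $\mathrm{FTR} = (\mathrm{IDs}_{E.coli,MBR} -
  \mathrm{IDs}_{E.coli,Indiv}) / (\mathrm{IDs}_{Total,MBR} -
  \mathrm{IDs}_{Total,Indiv})$.
  When matching *decreased* the human count while adding entrapment
  identifications, the rate is reported as 100%; when nothing was
  gained and that convention does not apply, the rate is undefined and
  excluded from means (the number of undefined replicates is reported).
  The count form is canonical; a set-difference variant
  (`ftr_variant = "sets"`) is available as a diagnostic, because counts
  and sets differ when matching both adds and removes identities.
* **ROC / AUROC** — sweeping every observed q-value as an acceptance
  threshold with human records as positives and entrapment records as
  negatives. The AUROC is computed by trapezoidal integration and is
  invariant under strictly monotone transforms of the q-value column.
* **Overlap (Szymkiewicz–Simpson) and Jaccard coefficients** — set
  similarity of two identification lists,
  $|A \cap B| / \min(|A|, |B|)$ and $|A \cap B| / |A \cup B|$. Overlap
  always dominates Jaccard; they coincide exactly when the two sets are
  equal or disjoint (for a strict subset the overlap is 1 while the
  Jaccard index is the size ratio — a useful reminder that the two
  coefficients answer different questions).

```{r ftr-example}
indiv <- tibble::tibble(replicate_id = "R1", ids_human = 1000L,
                        ids_entrapment = 0L, ids_total = 1000L,
                        mode = "indiv")
mbr <- tibble::tibble(replicate_id = "R1", ids_human = 1190L,
                      ids_entrapment = 10L, ids_total = 1200L,
                      mode = "mbr")
false_transfer_rate(mbr, indiv)   # 10 entrapment among 200 gained
```

## Filtering rules and their defaults

All thresholds live in `filter_config()` and have the workflow's
defaults: run-wise precursor q ≤ 0.01, global precursor q ≤ 0.01,
global protein-group q ≤ 0.01. The run-wise protein-group q-value
filter is **off** by default — it is not part of default filtering, but
a moderate cutoff (e.g. 0.05) measurably increases stringency in
co-analyses and is exposed as `pgq_run_max`. Count-based filters treat
"identified" as a non-missing intensity *after* q-filtering:
at least 500 proteins per cell (`filter_cells_min_proteins`), at least
3 replicates per group (`filter_min_group_replicates`; the default
`"any-group"` mode keeps a protein when any group reaches the count, so
each group remains testable on its own), and exclusion of proteins
observed in under 30% of cells (`filter_max_missing`). Contaminants are
removed by exact identifier match within the semicolon-split protein
group. Protein groups mixing the two species are labelled `"shared"`
and excluded from species-specific metrics rather than resolved by a
majority rule — with two proteomes there is no defensible tie-break.

## Quantification: exclude matching enhancers, then normalize

The pipeline order is fixed: q-value and contaminant filtering, *then*
exclusion of ME (and blank) runs, *then* normalization and protein
summarization. ME runs exist only to feed the matching library; they
are not analytes, and letting a 5–50× input run participate in
normalization or act as a sample downstream would distort every
condition summary. `pipeline_config()` rejects a configuration that
enables normalization without the exclusion stage.

`normalize_traces()` applies one additive shift per sample in log2
space, chosen so the median shared-ion log-ratio between each sample
and an anchor (the sample with the most observed ions) is zero. It is
idempotent, strictly shift-only (within-sample ion ratios are preserved
to the last floating-point ulp), and recovers pure loading differences
essentially exactly. `summarize_protein()` aligns each ion trace to the
protein's consensus trace by its median offset and takes the per-sample
median across aligned ions, damping single-ion outliers.

**Known limitation (by design):** any global median-ratio scaler
assumes the typical shared ion is unchanged between samples. Between
spike conditions this is false for *both* species — at 5% versus 20%
w/w spike the human background itself changes by
$\log_2(0.80/0.95) \approx -0.25$ — and the normalizer absorbs part of
that composition shift into its per-sample constants (how much depends
on the entrapment share of the detected ions, which sets the quantile
at which the mixture median sits). Observed between-condition ratios
after normalization are therefore compressed toward the
relative-to-background ratio rather than the design ratio. This is a
property of the method class, not of the implementation; comparing
conditions with identical composition (e.g. the same spike ratio at
different inputs) is unaffected.

A related empirical note: in a strictly multiplicative error model the
anchored median-ratio shift is insensitive to whether high-input runs
are present (their effect on analyte shifts is a common offset), so the
benefit of excluding MEs before normalization shows up in the
composition and downstream-sample-set arguments above rather than as a
loading-recovery penalty in simulation.

## Quality metrics

* `protein_cv()` — linear-scale sd/mean across replicates, n − 1
  denominator, requiring ≥ 2 observations by default (`min_obs`
  exposed; the source workflow does not state a minimum).
* `completeness_bins()` — proteins ranked by median log2 intensity,
  six near-equal bins (remainder to the top bins, ties broken by
  identifier for determinism), fraction of observed cells per bin.
* `ratio_deviation()` / `expected_log2_ratio()` — observed minus
  expected log2 ratios per protein, with the expectation
  $\log_2(\rho_b/\rho_a)$ (+ amount term) for the entrapment species and
  $\log_2((1-\rho_b)/(1-\rho_a))$ (+ amount term) for human.
* `sample_correlation()` — Pearson on pairwise-complete values with a
  minimum pairwise n (default 10, our choice, exposed).
* `pca_scores()` — samples decomposed on fully observed, row-centered
  proteins only.
* `dynamic_range()` — orders of magnitude spanned by median protein
  intensities.

## Single-cell analysis

`differential_expression()` performs a two-sided Student's t-test with
pooled variance by default — Welch is available by flag, but the pooled
test is the default because plain "Student's t-test" is the stated
method in the workflows this package reproduces — with significance
flagged at p < 0.05 and |log2 FC| > 0.95 (both configurable; a
Benjamini–Hochberg column is computed but flags use raw p-values by
default, matching volcano-plot practice). `impute_knn()` (mean of the
k = 5 nearest proteins over shared samples) and `impute_min()` (global
observed minimum) cover the two imputation strategies; neither ever
alters an observed cell. `zscore_rows()` centers at the row *median*
but scales by the usual n − 1 standard deviation about the mean — the
source workflows say "Z-score compared to the median" and nothing more,
so the conventional denominator is used.

`covariation_matrix()` correlates proteins observed in ≥ 20 cells over
their shared cells only (never after imputation), masking pairs with
fewer than 20 pairwise observations. `cluster_correlation()` clusters
the correlation-profile rows by Euclidean distance — undefined cells
are replaced by 0 (the neutral correlation) for the distance
computation only — with average linkage by default (the linkage is not
specified by the source method; single, complete and Ward are
available).

## The synthetic generators

`simulate_two_proteome()` emulates the spike-in design at the
report-table level: log-normal protein abundances (log2 N(14, 2.5)),
1 + Geometric peptide counts (mean 8), species weights $(1-\rho)$ and
$\rho$, input amounts in ng, per-run loading jitter (log2 sd
$\log_2 1.3$, about ±30%), multiplicative noise (log2 sd 0.24, implying
a median CV near 0.17, within the 0.16–0.19 range typical of
directLFQ-normalized low-input replicates), and logistic
intensity-dependent detection (midpoint 14, slope 1.5, so 1-ng-scale
runs identify roughly half of what 10-ng runs do — a qualitative, not
calibrated, input-depth relation). The default layout is seven
non-spiked 1-ng analytes plus triplicate 10-ng matching enhancers
spiked at 10%.

Matching: every feature missed in the first pass but present in the
co-analysis library is recovered with `true_transfer_prob` (0.6);
each matching event is independently a *false* transfer with
probability `false_transfer_prob` (default 0.002, the order observed
for well-controlled DIA software), in which case an entrapment library
feature not genuinely present in the run is recorded instead. This
makes the pooled FTR of the downstream estimator an exactly binomial
recovery of the injected rate. Genuine identifications draw q-values
from Beta(1, 200); false transfers draw from Uniform(0, 0.05), so a
fraction of them survives default filtering — false identifications
that were trivially separable by q-value would make the ROC analyses
pointless. No quantitative law links matching probability to ME input
amount; the saturation seen in real co-analyses is an empirical
observation, so the transfer probability is exposed as a parameter
rather than asserted as a law.

What the generator does *not* model: chromatography, ion mobility,
interference at the signal level, ratio compression, or shared tryptic
peptides between the proteomes (a flag can inject a nominal shared
fraction for testing the species-assignment rules). Passing tests on
synthetic data therefore validate the *post-processing logic*, not the
behavior of any search engine on real spectra.

`simulate_single_cells()` plants two co-expression modules loading with
opposite sign on one latent cell-state score (strong internal
correlation, mutual anti-correlation), an optional responder set
shifted by a fixed log2 effect in treated cells, and logistic
detection, yielding single-cell-like missingness concentrated in
low-abundance proteins.

## Numerical choices and degenerate inputs

Seeds are mandatory for both generators and fixed seeds give identical
output; generator calls restore the caller's RNG state. Undefined
FTRs are `NA`, excluded from means and tallied. FTRs outside [0, 1]
from mixed gains/losses are clipped with a warning. Ties in abundance
ranking break by protein identifier. Empty filter results are valid;
an all-ME table empties with a warning; a sample sharing no ions with
the normalization anchor, an all-missing matrix to `impute_min()`, a
single-class ROC and a zero-identification FPR are errors naming the
problem. Test-suite problem sizes (hundreds of proteins, tens of
runs/cells; 10,000 proteins for the null-calibration check) are chosen
to make distributional checks stable at a few seconds per test.

## Reproducing the packaged checks

The testthat suite regenerates every fixture in code. The script
`scripts/acceptance.R` recomputes the package's worked-example quantity
(the degenerate-count FTR convention, reported in percent) and writes
it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
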