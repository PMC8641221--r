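---
title: "Methods: integrated multi-omics enrichment with integromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated multi-omics enrichment with integromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integromics)
```

This vignette documents the statistical model behind `integromics`, the
choices made where the design was genuinely open, and what the synthetic
studies used in the test suite do and do not demonstrate about real data.

## Study design and data model

The package targets two-group designs (labelled *control* and
*treatment*) with small per-group sizes; the reference design throughout
is n = 5 per group, the typical scale of a nonhuman-primate feeding
study. Four layers are modelled:

* **transcript, miRNA** — integer read counts; no missing values allowed.
* **protein, metabolite** — positive MS intensities; an empty cell means
  *not identified*, which is deliberately distinct from a measured zero
  because the proteomics presence filter branches on identification, not
  abundance.

Molecule identity is the bare symbol string, case-sensitive. Transcripts,
proteins and miRNA targets share the gene-symbol space, so the same
symbol measured on two layers is one molecule; metabolites are identified
by name. This follows the convention of symbol-level cross-layer matching
and deliberately avoids any ortholog or identifier mapping: inputs are
assumed pre-harmonized.

## Per-layer differential abundance

All layers end in a two-sided pooled-variance t-test with
`n1 + n2 - 2` degrees of freedom and an **unadjusted** threshold of
`alpha = 0.05`. Unadjusted testing at this scale is a deliberate,
power-preserving choice for small-n discovery work whose downstream
inference happens at the pathway level; `run_layer(..., adjust = "BH")`
switches the differential flag to Benjamini–Hochberg-adjusted p-values
for analysts who want per-feature error control.

**Count layers.** Features with zero counts in every sample are removed
(a single read anywhere retains the feature). Samples are then scaled by
trimmed-mean-of-M-values (TMM) factors: the reference sample is the one
whose library-size-scaled upper quartile is closest to the mean of upper
quartiles; each sample's factor is the precision-weighted mean of log2
ratios against the reference after trimming 30% of log-ratios and 5% of
average log-intensities from each tail, and factors are centered to
geometric mean 1. Tests run on counts per million of the factor-adjusted
library sizes. The miRNA layer follows the transcript chain unchanged —
the normalization method for small RNA counts is not separately
specified anywhere authoritative, and mirroring the transcript treatment
is the least surprising default.

**Protein layer.** Presence filtering retains proteins observed in at
least `ceiling(0.6 * n)` samples of *each* group (3 of 5 in the reference
design) as testable, plus the group-exclusive branch: proteins observed
in every sample of one group and none of the other are retained as
differential with direction `exclusive_treatment` / `exclusive_control`,
a ratio sentinel of `+Inf` / `-Inf`, and no test statistic. Exclusive
proteins count toward enrichment like any other differential molecule —
membership is meaningful even where a fold change is not. Intensities
are natural-log transformed and missing cells (at most `n - 3` per group
per feature by construction) are filled by sequential regression
imputation *within each group*: features ordered by increasing
missingness, missing cells initialized at the feature's group mean, then
each incomplete feature regressed on all other features by minimum-norm
least squares and updated, sweeping until the largest update falls below
`1e-6` or 100 sweeps. Observed values are never altered and complete
data pass through untouched. The published description of sequential
imputation does not pin down these internals; the ordering,
initialization, tolerance and iteration cap above are this package's
fixed contract, and the minimum-norm (pseudoinverse) solver is the
natural resolution of the feature-on-features regression when features
far outnumber samples.

A consequence worth stating plainly: **deterministic imputation followed
by an unadjusted t-test is anti-conservative.** Imputed cells carry no
residual noise, within-group variance shrinks, and on null data with 10%
missing cells the protein chain rejects at roughly twice the nominal
rate (the test suite asserts the direction of this effect). This is a
property of the impute-then-test recipe itself, not of the solver — mean
imputation behaves the same way. Calibration checks in this package
therefore run the protein chain on complete null data, and protein
p-values from imputed features should be read as exploratory.

**Metabolite layer.** Optional pre-treatment divides by an internal
standard (when one is named), median-normalizes per sample, and takes
log2 — the standard treatment for ratio-scaled MS intensities; it can be
turned off for data already on a comparable scale. Selection is the
strict joint rule: differential iff `p < 0.05` *and* `VIP > 1`. The VIP
comes from a one-predictive-component projection to latent structures
fit of the autoscaled features against the centered group indicator. An
orthogonalized (OPLS-style) fit with a single binary response has the
same single predictive component, so the one-component PLS VIP is the
standard surrogate; for one component `VIP_j = sqrt(P) |w_j| / ||w||`,
which forces `mean(VIP^2) = 1` — the test suite checks this identity and
agreement with an independent PLS-DA implementation.

**Clinical summaries.** `ttest_from_summary()` applies the identical
pooled-variance test to printed group means, SDs and sizes, so published
clinical tables can be checked or extended without raw data;
`inst/extdata/clinical_summary.tsv` ships a two-diet-group (chow vs
high-fructose, n = 5 + 5) primate clinical-chemistry table in this form.

## Enrichment and the integration mechanism

An *analysis set* fixes the Fisher components for one layer combination:
the universe `N` (all molecules passing quality filters, symbols
deduplicated across gene-level layers), the analysis-ready list `n`
(molecules differential in at least one included layer — a molecule
counts once however many layers flag it), per-pathway `K` (members in
the universe) and `k` (differential members passing the connection
requirement). The p-value is the hypergeometric right tail
`P(X >= k)`, computed by `stats::phyper` on the log-gamma scale; `k = 0`
gives exactly 1. Pathways with `K = 0` are skipped with a note rather
than reported at p = 1.

**Direct connections.** Only differential molecules incident to a
knowledge-base edge whose other endpoint is also differential count
toward `k`. The scope of "directly connected" is genuinely ambiguous:
the default (`connection_scope = "global"`) accepts a partner anywhere in
the differential set, which explains how adding a second layer can
*connect additional molecules into* a pathway; the stricter
`"pathway"` scope requires the partner inside the same pathway. Both are
implemented; neither is claimed to replicate any proprietary tool's
internals.

**Why integration moves p-values.** Appending analysis-ready molecules
that map into no pathway grows `n` and `N` together, and the overlap of
a larger draw from a larger universe is stochastically larger, so every
pathway's right-tail p can only rise — a coupling argument makes this
exact, and the acceptance suite verifies it on 1,000 random instances.
Conversely, appending quality-passing but non-differential molecules
grows only `N` and can only lower p-values. A real added layer does
both at once, and the net direction for an individual pathway depends on
whether its own `k` grows — which is precisely why the comparison across
layer combinations is informative. Note the one-sided claims hold for
the two pure cases only; an arbitrary mixture has no universal
direction, so the package's monotonicity checks are formulated on the
pure cases.

**Direction conflicts.** When the same symbol is differential up in one
layer and down in another, the protein direction takes precedence over
the transcript (protein abundance is the closer proxy for function), the
molecule is recorded in the set's `conflicts`, and sign-consistency
scoring excludes it while overlap counting keeps it: membership is
well-defined even when direction is not.

Significance is reported at `p < 0.05` with a stricter `p < 0.01` flag
alongside; no multiple-testing correction is applied across pathways,
mirroring the unadjusted design of the per-feature stage.

## Regulator activation

Candidate regulators are the sources of signed `regulates` edges. For
regulator analysis only tissue-evidenced edges are kept (the
liver-evidence requirement), and regulators left without edges drop out.
Overlap significance uses the same Fisher machinery (`K` = direct
targets in the universe, `k` = differential direct targets). The
activation score over the `m` direction-resolved differential targets is
`z = sum(edge_sign * direction_sign) / sqrt(m)`, so `|z| <= sqrt(m)` and
all-consistent targets give `sqrt(m)` exactly. A call requires both
`p < alpha` and `|z| >= z_min`; `z_min = 2` is the conventional
threshold and is exposed as an argument. Calls never require the
regulator itself to be measured, let alone differential — regulator
activity is routinely post-translational.

## miRNA pairing

Differential miRNAs are paired with differential gene/protein targets of
strictly opposite direction over targeting edges whose evidence is
`validated` or `high_predicted`; `low_predicted` edges never pair.
Evidence is a knowledge-base attribute — no target prediction is
computed. Pairs are merged into already-significant pathways and
networks by target membership, counted with and without miRNAs, and
never change a p-value: the pairing layer annotates, it does not test.
Pairs matching no significant set are listed as unassigned rather than
dropped.

## The synthetic-study generator

`sim_config()` fixes the study conditions; `make_knowledge_base()` and
`simulate_layers()` realize them deterministically from one master seed
(each stage derives a sub-seed, so regenerating any piece is
reproducible and `write_fixture_set()` is byte-stable).

Generative choices, made once:

* **Counts** are negative-binomial around lognormal baselines
  (`meanlog = 5`, `sdlog = 1`, dispersion 0.1) with per-sample depth
  multipliers uniform on [0.7, 1.3] — the minimal standard model for
  RNA-Seq-like data that still exercises TMM.
* **Intensities** are lognormal (`meanlog = 14`, `sdlog = 1`) with
  0.25 SD per-cell log noise, matching the ratio-scaled character of MS
  data.
* **Default sizes** — 2,000 transcripts, 800 proteins (the first 800
  gene symbols, so layers overlap), 300 metabolites, 150 miRNAs, 25
  pathways of 10–30 members with ~15% metabolite membership — are
  deliberately a few-fold smaller than a real study so that full
  pipelines, 50-seed recovery studies and null-calibration suites all
  run in seconds; they are large enough that per-layer binomial bands
  and pathway rankings are meaningful.
* **Planted signal**: three pathways at log2 fold change 2 on 80% of
  members; two regulators (one activated, one inhibited) with 12-target
  programs at |log2 FC| 2 drawn from genes outside all pathways so
  pathway and network recovery stay separable; ten planted miRNAs
  targeting affected genes, 80% of them inverse at |log2 FC| 1.5; four
  group-exclusive proteins; 10% missing-at-random protein cells.
  Recovery acceptance runs weaken the pathway signal to effect 1.5 on
  60% of members.

What passing these tests shows — and does not. The generator draws
independent features, so the null-calibration bands certify the test
machinery, not robustness to the correlation structure of real tissue.
It plants clean, pathway-concentrated shifts, so recovery rates certify
that the pipeline finds what its model class expects, not sensitivity to
diffuse or partially opposing real signals. It simulates neither batch
effects nor intensity-dependent missingness (its protein missingness is
MAR plus explicit group-exclusives). Real-study headline counts are not
reproducible from code at all — they require the original raw data and
a proprietary knowledge base — which is exactly why the test suite is
property-based.

## Numerical and degenerate-input conventions

* Zero pooled variance: the t statistic is returned as `NA` and flagged,
  never thrown.
* Zero-variance features in the VIP fit get VIP 0 with a warning.
* `fisher_right_tail` validates `0 <= k <= min(K, n)` and `K, n <= N`
  and errors on inconsistent counts; `k = 0` returns exactly 1.
* TMM factors are exactly 1 for samples identical to the reference
  (log-ratio spread below `1e-6`); an all-zero sample is an error.
* Imputation refuses features missing more than `n - 3` values in a
  group, naming the offender; group-exclusive proteins must be filtered
  out beforehand (as `run_layer` does).
* Ties in enrichment ordering are broken by pathway id for
  reproducibility.

## Interfaces

The exported functions are the interface; `run_pipeline()` composes them
in the fixed schedule (each single layer, transcript+protein,
transcript+protein+metabolite, miRNAs merged last) and audits every
reported count against its own tables before returning. All file formats
are plain text: GMT pathway sets; TSV edge lists
(`source target sign relation tissue_evidence`), miRNA target tables
(`mirna target evidence`), trait tables (`gene trait variant`), group
maps, and feature-by-sample matrices with blank cells for missing;
configurations are YAML. Writers emit UTF-8 with LF endings, and every
reader rejects each documented invariant violation with a located error.
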