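---
title: "Methods: fraction-resolved translational fate analysis"
author: "polysomeFate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fraction-resolved translational fate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysomeFate)
```

This vignette documents the statistical model, the tunable parameters,
the synthetic-data generator and the numerical/design choices behind
`polysomeFate`. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

# Data model

The unit of data is a gene × sample matrix of raw read counts in which
each sample is one sequencing library: one of ten equal-volume sucrose
gradient fractions (F1–F10) of one developmental stage and replicate, or
a whole-transcriptome ("total") library. The `FractionExperiment` class
(a `SummarizedExperiment`) validates non-negative integer counts, unique
gene ids, known stage/compartment labels and unique
(stage, compartment, replicate) triples. The stage axis is configuration,
never inferred from data, because lag arithmetic (differences of stage
indices) must be deterministic; the default axis is GV, MII, zygote,
2-Cell, 4-Cell, 8-Cell, morula, blastocyst.

Fractions group into layers by ribosome load: free RNA (F1–F2), monosome
(F3–F5), polysome (F6–F10), plus the transcriptome layer from total
libraries.

# Layer construction

For each layer, stage and replicate, member-fraction raw counts are
summed per gene, the summed library is scaled to counts per million, and
replicates are averaged on the log2(CPM + 1) scale.

Two choices deserve comment:

* **Sum-then-CPM rather than averaging per-fraction CPM.** Equal-volume
  fractions carry very different RNA mass; summing raw counts weights
  each fraction by its actual signal, whereas averaging per-fraction CPM
  would give a nearly empty fraction the same weight as a full one. The
  alternative remains available (`aggregateLayers(..., perFractionCPM =
  TRUE)`).
* **Replicate averaging on the log scale with pseudocount 1.** Low-input
  libraries have heavy-tailed counts; log-averaging stabilises the
  influence of single replicates.

Standardization for time-course clustering is the usual per-gene z-score
across stages with the sample (n − 1) standard deviation; rows with
numerically zero variance are excluded (they carry no temporal signal)
and reported.

# Fuzzy c-means

Soft clustering is the natural choice for short, noisy expression time
courses: genes on cluster boundaries receive split memberships instead
of arbitrary hard labels. The implementation is the classical alternating
scheme with Euclidean distances. Numerical details that matter:

* memberships are computed from distances scaled by the per-row minimum,
  so small fuzzifiers (large exponents `2/(m-1)`) cannot overflow;
* a point at exactly zero distance from a center takes crisp membership
  on the first such cluster (by index), a deterministic tie-break;
* convergence is declared when the largest center displacement falls
  below `tol` (default 1e-8) and is capped at `maxIter` (default 300);
  hitting the cap returns the model with a warning rather than failing,
  since near-converged models are usable;
* a center that loses essentially all membership mass keeps its previous
  position instead of producing NaN;
* the objective J~m~ is recorded each iteration and is non-increasing —
  asserted in the tests on every run.

**Fuzzifier default m = 1.25.** Standardized 8-point profiles live on a
small sphere; fuzzifiers near 2 wash memberships out toward 1/c there,
while values near 1.25 keep cluster cores crisp enough for a 0.5
membership cutoff to be meaningful. `m` is exposed everywhere.

**Initialization.** Generic clustering draws c distinct data rows as
starting centers, with 10 seeded restarts keeping the lowest final
objective — fuzzy c-means is initialization-sensitive and restarts are
cheap at these sizes. Mode decomposition (below) instead initializes at
the six canonical templates: the intended optimum is known up to noise,
template starts make the fit deterministic given the data, and they
prevent the known failure mode in which two near-identical template
clusters (e.g. those differing only in total expression) merge while a
heavily populated region splits.

**Cluster counts.** c = 6 for the per-stage mode decomposition (six
selectivity modes) and c = 12 for per-layer temporal clustering (twelve
temporal patterns); both configurable.

# Selectivity modes and broad groups

At each stage, each gene's feature vector is the triple of its
(transcriptome, monosome, polysome) layer levels, z-scored across genes
per layer — "high" or "low" is always relative to the other genes at
that stage. The six canonical templates over these features, encoded
low/mid/high = −1/0/+1, are:

| Mode | transcriptome | monosome | polysome | reading |
|------|---------------|----------|----------|---------|
| 1 | low | high | low | monosome-specific (storage) |
| 2 | mid | high | high | monosome + polysome |
| 3 | low | low | high | selective translation, low-abundance |
| 4 | mid | mid | high | selective translation, modest-abundance |
| 5 | high | high | high | active translation, highly expressed |
| 6 | high | low | low | highly transcribed, untranslated |

Fitted centers are matched one-to-one to templates by maximizing total
cosine similarity over all 720 assignments (exhaustive search; ties break
to the lexicographically smallest permutation; all-equal centers are an
error, since no mode structure exists). Genes take the mode of their
top-membership cluster when that membership reaches the core threshold
(default 0.5), else they stay unassigned. Modes map deterministically to
broad groups: 1 → monosome-specific, 2–5 → actively translated,
6 → untranslated. Stage-to-stage flow tables count broad-group
transitions over genes assigned at both stages; genes unassigned at
either stage are excluded from the flow and reported separately.

# Delayed translational activation

Temporal clustering is run separately on the monosome and polysome layer
matrices after a flat-profile filter: genes whose across-stage log2 sd
falls below 1 (default, configurable) have no temporal signal worth
clustering and would otherwise accumulate cluster centers near the
origin. A gene's peak stage in a layer is the peak stage of the
cluster(s) it belongs to, with one refinement: memberships of clusters
whose centers peak at the same stage are pooled before applying the core
threshold. With c above the number of distinct peak stages, two
near-duplicate centers can otherwise sit on one peak and split a gene's
membership to ~0.5/0.5, dropping it below threshold even though its peak
stage is unambiguous. Peak-stage pooling removes exactly this artifact
and nothing else. When a gene clears the threshold at several peak
stages of one layer, the earliest peak is used (deterministic
tie-break).

The lag call is then the peak-index difference: lag0 (same stage), lag1
(polysome one stage after monosome), lag2 (two stages after); every
other pattern — including polysome peaks preceding monosome peaks — is
classified `none`, with the signed offset retained in an auxiliary
column. Peak stages are defined on cluster centers rather than on
individual noisy profiles; this is deliberately noise-robust.

Core overlap between monosome and polysome stage-specific clusters is
reported as raw counts plus a one-sided hypergeometric upper-tail
p-value given core sizes and universe size; the p-value is an extension
over raw counts, which are not comparable across unequal core sizes.

# Polysome-versus-monosome occupancy test

Per stage and replicate, counts are summed over F6–F10 and over F3–F5;
each summed library is CPM-normalized; per gene a Welch two-sample
t-test compares replicate log2(CPM + 1) values between groups. The
log2 fold change is the polysome-minus-monosome mean difference. Genes
with CPM below 1 in every replicate of both groups are excluded before
testing; BH adjustment runs across the tested genes.

Choices:

* **Welch-t on log CPM rather than a negative-binomial GLM.** With three
  replicates per group and the validation surface being calibration on a
  planted null (not replication of a particular GLM's output), the
  self-contained t-test is preferable: its null behaviour is verified
  directly (false-positive rate at α = 0.05 on 5000 planted-null genes,
  asserted within [0.02, 0.08]) and its power at a planted 8-fold shift
  exceeds 0.8 by a wide margin. Externally computed p/log2FC tables can
  be substituted at the `switchGenes()` level, which consumes plain
  result tables.
* **FDR < 0.05, not raw p < 0.05.** Both conventions circulate for this
  kind of call; the package defaults to the FDR (`useFdr = FALSE`
  switches), with fold change > 2 applied to the point estimate (no
  shrinkage model is fitted, so none is applied).
* Group aggregation before testing (not per-fraction testing): the
  scientific contrast is layer-level occupancy.

Switch ("active") genes of a transition (s, s+1) are those called
`mono_up` at s and `poly_up` at s+1.

# Cross-omics integration

Companion tables (protein log-intensity, poly(A) tail length, binary m6A
flags) are gene × stage matrices; dataset-specific stage names map onto
the axis via a user-editable alias table, and gene matching is by
identifier only. Correlation between polysome level at stage s and a
companion at stage s′ is rank-based by default (the modalities live on
incommensurate scales); every (s, s′) cell is computed over shared genes
with finite values, flagged missing below 10 genes.

`bestLag()` reports, per polysome stage, the companion stage maximizing
the correlation (ties to the earlier companion stage, flagged), and
summarises the modal lag as a magnitude with a direction:
`companion_lags` when the companion trails the polysome signal (protein
accumulates after translation) and `companion_leads` when it precedes it
(poly(A) tails lengthen before translational activation). The magnitude
+ direction convention is used because the two companion modalities sit
on opposite sides of the polysome signal in time; a single signed number
would force an arbitrary orientation.

Binary m6A data are handled by set arithmetic instead of correlation:
per layer and stage, the percentage of the stage-specific gene set
carrying an m6A flag at that stage.

# The synthetic-data generator

The generator emulates the fraction-resolved study design end to end:
8 stages × (10 fractions + 1 total library) × 3 replicates, 1200 genes,
~2 × 10^6^ expected reads per library, negative-binomial counts with
shared dispersion φ = 0.05 (variance μ + φμ²) — a two-parameter noise
model standard for RNA-seq counts. Fraction allocation is
multinomial-in-expectation: a gene's planted layer masses are divided
equally over member fractions and scaled into per-library NB means,
preserving NB marginals per library.

Planted structure:

* **Levels.** Low/mid/high planted log2 abundances are 3/6/9 — 3 log2
  units apart, far enough that the six modes separate cleanly after
  standardization — with gene-level noise sd 0.4 (a modest biological
  spread around the template) plus per-stage jitter sd 0.2.
* **Static mode genes** (the `none` lag class, 64% by default) hold one
  template constantly; optional `modeSwitches` plant exact flow-table
  transitions.
* **Dynamic lag genes** (lag0/lag1/lag2, 12% each) have mid total
  expression throughout, low monosome/polysome baseline, and a high peak
  at the planted stage(s); their free-layer signal peaks one stage before
  monosome loading, mirroring the appearance of transcripts in the free
  layer before ribosome recruitment. Their per-stage planted mode
  follows by nearest-template lookup and is unique by construction:
  mode 6 off peak, mode 1 at a monosome-only peak, mode 3 at a
  polysome-only peak, mode 2 at a joint peak. This makes mode truth and
  lag truth mutually consistent, so one dataset validates both analyses.
* **Companions.** Protein = polysome trajectory `proteinLag` (default 2)
  stages earlier plus Gaussian noise (sd 0.5 log2); poly(A) length is an
  affine function of the polysome trajectory `polyALag` (default 1)
  stages later plus noise, floored at 10 nt; m6A flags are Bernoulli
  with baseline 0.2, tripled for polysome-assigned genes at zygote and
  2-Cell. Stage indices clamp at the axis ends.
* `simulateNullPair()` builds a single-stage design in which every null
  gene allocates equal mass to F3–F5 and F6–F10 (true group log2FC
  exactly 0); spiked genes receive ±`effectLog2FC` in equal numbers so
  library depths stay balanced and planted effects are not distorted by
  depth normalization.

A single integer seed governs all draws; the truth object carries the
planted per-gene lag classes, peak stages, per-stage mode matrix and
log2 layer trajectories, and `truthLagOracle()` re-derives the lag
classes from the peaks as the generator's internal consistency check.

**What the generator does not emulate** — and hence what passing tests
do not certify about real data: batch effects, cross-contamination
between adjacent fractions, gene-specific dispersions, library-size
variation, partially overlapping gene universes across modalities,
ortholog/alias mismatches, and modes that are genuinely ambiguous
mixtures rather than template-plus-noise. Recovery rates on real data
will be lower than on planted truth; the synthetic results certify the
pipeline's correctness, not effect sizes in any particular embryo
dataset.

# Problem sizes and determinism

The test suite and acceptance script run the full design (1200 genes,
264 libraries) for end-to-end recovery; the enrichment null uses 5000
genes and power uses 1000 spiked genes in a 2000-gene background; the
clustering reference fixture is two 100-point blobs at ±5 with sd 0.5;
hypergeometric p-values are verified exhaustively against explicit
enumeration for all universes up to 25; determinism checks use a
400-gene pipeline run executed twice, a size at which every module
(including both clustering passes) is exercised. `runAll()` expands its
single seed into fixed per-module substreams, writes the serialized
configuration next to the outputs, and hashes every output file into a
manifest, so a run is reproducible from its artifact directory alone and
reproducibility is checkable by manifest comparison.

# Known limitations

* Mode labeling requires exactly six clusters; other c values cluster
  but cannot be mode-labeled.
* Peak-stage resolution is bounded by the stage axis; sub-stage dynamics
  are invisible.
* The occupancy test treats fractions within a group as one pooled
  library; fraction-level heterogeneity within F6–F10 (light vs heavy
  polysomes) is out of scope.
* Companion integration assumes shared gene identifiers; no ortholog or
  alias resolution is attempted.
* Detection cutoffs (CPM ≥ 1) are conventions, not estimates; gene
  totals per stage depend on them.
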