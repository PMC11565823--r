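# polysomeFate

Fraction-resolved translational-fate analysis for polysome-profiling time
courses.

## The problem

Low-input ("scarce sample") polysome profiling separates a lysate on a
sucrose gradient into ten equal-volume fractions (F1–F10) ordered by
ribosome load and sequences each fraction separately, alongside
whole-transcriptome libraries. Across a developmental time course — here
modelled on mouse oocyte maturation and pre-implantation development (GV,
MII, zygote, 2-Cell, 4-Cell, 8-Cell, morula, blastocyst) — this resolves
*where* each mRNA sits translationally at each stage: free of ribosomes
(F1–F2), monosome-bound (F3–F5, often storage or paused initiation), or
polysome-bound (F6–F10, active translation).

`polysomeFate` is for analysts who have such fraction-resolved count
matrices and want to characterise mRNA translational fate: which
selectivity mode a gene occupies at each stage, how genes flow between
modes across development, whether polysome occupancy trails monosome
occupancy by one or two stages (delayed translational activation), which
genes switch from monosome- to polysome-enriched across a developmental
transition, and how polysome occupancy relates — possibly with a stage
lag — to protein abundance, poly(A) tail length and m6A status.

## The model in brief

* **Layers.** Per layer ℓ, stage *s* and replicate, member-fraction raw
  counts are summed, scaled to CPM, and replicates are averaged as
  log2(CPM+1), giving gene × stage matrices for free, monosome, polysome
  and transcriptome layers.
* **Fuzzy c-means.** Standardized profiles *z<sub>g</sub>* are clustered
  by minimising
  *J<sub>m</sub>* = Σ<sub>g</sub>Σ<sub>j</sub> u<sub>gj</sub><sup>m</sup> ‖z<sub>g</sub> − v<sub>j</sub>‖²
  with memberships
  u<sub>gj</sub> = [Σ<sub>k</sub>(d<sub>gj</sub>/d<sub>gk</sub>)<sup>2/(m−1)</sup>]<sup>−1</sup>,
  fuzzifier *m* = 1.25 by default. Cluster cores are genes with
  membership ≥ 0.5 (guaranteed disjoint).
* **Selectivity modes.** At each stage, the (transcriptome, monosome,
  polysome) triple is z-scored across genes and decomposed into six
  canonical modes — 1: monosome-specific; 2: monosome + polysome;
  3/4: selective translation of low-/modest-abundance mRNAs; 5: active
  translation of highly expressed mRNAs; 6: highly transcribed but
  untranslated — by cosine-matching cluster centers to level templates.
  Modes collapse to three broad groups (monosome-specific / actively
  translated / untranslated) for stage-flow (Sankey-style) accounting.
* **Delayed activation.** Temporal clustering (c = 12) of monosome and
  polysome layers gives per-gene peak stages; the polysome−monosome peak
  offset classifies genes as lag0/lag1/lag2 (or none).
* **Occupancy switches.** Per stage, Welch *t*-tests on log2(CPM+1) of
  group-aggregated F6–F10 vs F3–F5 counts with BH-FDR < 0.05 and
  fold change > 2 call `poly_up`/`mono_up`; genes `mono_up` at stage *s*
  and `poly_up` at *s*+1 are the transition's switch ("active") genes.
* **Cross-omics lags.** Rank correlations between polysome level at stage
  *s* and a companion modality at stage *s′*, over all (s, s′), with the
  modal best-lag summarised per modality; per-layer m6A percentages for
  stage-specific gene sets.

A seeded negative-binomial simulator (`simulateDataset()`) generates the
whole design — 1200 genes × 8 stages × 11 libraries × 3 replicates — with
planted modes, lag classes and companion lags, so every analysis above can
be validated against ground truth.

## Worked example

```r
library(polysomeFate)

sim    <- simulateDataset(simulationConfig(seed = 1))
layers <- aggregateLayers(sim$experiment)
layers$polysome
#> LayerMatrix 'polysome': 1200 genes x 8 stages (log2(CPM+1))

modes <- assignModesAllStages(layers, seed = 2)
table(factor(modes$modeMatrix[, "2-Cell"], levels = 1:6))
#>   1   2   3   4   5   6
#> 163 185 119 177  99 457

rec <- modeRecovery(modes$modeMatrix, sim$truth$modeMatrix)
sprintf("mode recovery: %.1f%% of %d assigned gene-stages", rec$percent, rec$nAssigned)
#> "mode recovery: 96.9% of 9596 assigned gene-stages"

res <- polyVsMonoTest(sim$experiment, "2-Cell")
head(res[order(res$fdr), ], 3)
#>      gene_id  stage log2fc        p      fdr    call
#> 212 gene0212 2-Cell   3.62 3.62e-08 1.26e-05 poly_up
#> 531 gene0531 2-Cell  -6.20 4.18e-08 1.26e-05 mono_up
#> 917 gene0917 2-Cell  -6.66 1.26e-08 1.26e-05 mono_up

bestLag(laggedCorrelation(layers$polysome, sim$companions$protein))$summary
#> $modal_lag  [1] 2      # protein trails polysome occupancy by two stages
#> $direction  "companion_lags"
#> $mean_r     0.908
```

The mode table says that at the 2-Cell stage 457 genes are in mode 6
(highly transcribed but untranslated — the transcriptional burst of
embryonic genome activation outrunning translation), while 580 genes
(modes 2–5) are actively translated. The occupancy test finds genes more
than 2-fold polysome- or monosome-enriched at FDR < 0.05, and the lag
summary recovers the planted two-stage delay between polysome occupancy
and protein accumulation.

`runAll(runConfig(outDir = "out"))` executes the whole pipeline and
writes every result table, the serialized configuration and an MD5
manifest to `out/`.

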