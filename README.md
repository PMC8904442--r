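# mitomix

Identify clonally informative mitochondrial DNA variants in single-cell
sequencing data, and use them to recover the clonal structure of a cell
population.

Mitochondrial heteroplasmy — the allele fraction of an mtDNA variant within
a cell, anywhere between 0 and 1 — is inherited through cell division, which
makes mtDNA variants cheap endogenous lineage barcodes in scRNA-seq,
scDNA-seq and scATAC-seq. The hard part is that candidate variant lists from
per-cell pileups (e.g. cellSNP-lite output) contain tens of thousands of
sites, almost all of them sequencing error or transient mutation. `mitomix`
is for analysts who have such a variants × cells pair of AD/DP count
matrices and want the short list of variants whose heteroplasmy genuinely
differs between subpopulations of cells.

## The statistic

For each variant, the per-cell alternative-allele counts are modelled two
ways:

* **M0** — one binomial rate shared by all cells:
  `AD_j ~ Binom(DP_j, θ)`; MLE `θ̂ = ΣAD/ΣDP` (1 parameter).
* **M1** — a two-component binomial mixture: a fraction `π` of cells carry
  the variant at heteroplasmy `θ1`, the rest sit at background `θ0`
  (3 parameters; maximised by EM with restarts).

With `BIC = n_par · log(n_cells) − 2 log L`, each variant is scored by

```
ΔBIC = BIC(M0) − BIC(M1)
```

Large ΔBIC means one shared rate cannot explain the across-cell
heterogeneity — the signature of a clonally informative variant. A cutoff
is placed automatically at the knee of the cumulative distribution of ΔBIC
(Kneedle: the point of maximum height above the diagonal of the normalised
curve), and cells are optionally clustered on the selected variants with a
binomial-mixture EM to produce per-cell clone posteriors.

The package also contains a count-level simulator of the benchmark design
(clonal lineage trees, log-normal clonal allele frequencies, elevated-noise
sites, uneven on/off-target coverage) and PR/ROC benchmarking utilities, so
the whole pipeline is testable end-to-end without any external data.

## Worked example

Simulate the benchmark setting (90 cells, 3 equal clones, 50 clonal
variants per clone, branched tree, ~3500 elevated-noise sites), score every
candidate variant, place the knee cutoff, and assign clones:

```r
library(mitomix)

sim  <- simulateClones(simConfig(variants_per_clone = 50L, rng_seed = 1L))
sim
#> MitoSimulation: 29031 candidate variants x 90 cells (150 clonal, 3 clones)

fits <- fitDeltaBIC(simCounts(sim), fitConfig(rng_seed = 1L))
kr   <- findKnee(fits$delta_bic)
kr
#> KneeResult: threshold 264.7; 252 / 29031 variants selected

ev <- prRoc(fits$delta_bic, simTruth(sim)$isClonal)
ev
#> RankingEval: AUPRC = 1.0000, AUROC = 1.0000 (10354 thresholds)

operatingPoint(fits$delta_bic, simTruth(sim)$isClonal, kneeThreshold(kr))
#> precision    recall
#> 0.5952381 1.0000000

ca <- fitClones(simCounts(sim)[selectedMask(kr), ], K = 3,
                fitConfig(rng_seed = 1L))
cloneConcordance(ca, cloneLabels(sim))$concordance
#> [1] 1
```

Reading: all 150 planted clonal variants rank above every noise site
(AUPRC/AUROC 1.0); the knee threshold (ΔBIC > 265) recovers all of them
(recall 1.0) along with a tail of elevated-noise sites (precision 0.60);
clustering cells on the selected variants reproduces the planted clone
labels exactly. On real data the same objects come from
`readCellSNP("path/to/cellSNP_dir")` instead of the simulator, with
`applyBlacklist()` available for the error-prone rCRS regions 302–315,
513–525 and 3105–3109.

The same pipeline is available from the shell:

```sh
mitomix simulate --out sim_dir --variants-per-clone 50 --seed 1
mitomix fit --cellsnp sim_dir --out run_dir --clones 3 --seed 1
mitomix benchmark --deltabic run_dir/deltaBIC.tsv --truth sim_dir/truth.tsv
```

`fit` writes `deltaBIC.tsv` (per-variant fits and selection), the selected
AD/DP matrices in cellSNP-lite layout under `passed/`, a knee diagnostic
PNG and a JSON run manifest; reruns with identical inputs and seed are
byte-identical.

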