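# pdmg — cross-modality consensus signatures of disease microglia

`pdmg` is an R package for a question that comes up whenever several
transcriptomic views of the same disease exist: *do they agree, and can
their agreement be found back in tissue?* It implements, as a tested
pipeline, the chain that (1) derives differential expression from bulk
RNA-seq of mutant vs isogenic microglia-like cells and from single-nucleus
RNA-seq of patient midbrain, (2) condenses the two into a **consensus
disease-microglia signature** — a directional gene list supported by both
modalities through shared enriched gene sets — and (3) classifies
individual microglia in targeted spatial transcriptomics data as
**consensus** or **non-consensus** cells by per-gene directional
concordance with that signature. It is written for computational biologists
who want each stage to be a small, verifiable statistical operation rather
than a black box.

Because the motivating datasets are not freely downloadable, the package
includes a first-class synthetic-data module that generates all three
modalities with planted ground truth (signature genes and directions,
cell-type proportions, a dominant GFAP-like gene, a consensus
subpopulation at a known rate), so every stage is validated by parameter
recovery.

## The core statistics

* **Bulk DE** — negative binomial likelihood-ratio test per gene:
  group-specific vs common mean, log link, TMM-scaled library offsets,
  pooled method-of-moments dispersion, χ²₁ reference; BH FDR.
* **Single-cell DE** — Wilcoxon rank sum on log2-CPM per cell (library-size
  normalization), with an exact enumeration path that is correct under
  ties: U = #{xᵢ > yⱼ} + ½·ties, two-sided p = 2·min(tails).
* **Signature** — hypergeometric over-representation per gene set in each
  modality; sets significant in **both** and containing significant genes
  from **each** survive; the signature is the union of their significant
  genes, with direction conflicts excluded and logged.
* **Deconvolution** — non-negative least squares
  min‖W^½(b − Mp)‖, with M the donor-averaged cell-type profiles scaled by
  mean library size and W the inverse cross-donor variance (+ε); p
  normalized to proportions.
* **Spatial** — transcript-to-cell assignment by label-mask lookup with
  ≤8 px nearest-label expansion; removal of any gene holding >40% of all
  transcripts; clustering on the 10 most variable genes (5 PCs, k-means,
  silhouette-chosen k); marker-based annotation.
* **Classification** — a disease microglial cell is *consensus* iff the
  signs of its deviations from the healthy-microglia reference match the
  signature direction for at least a fraction τ of the evaluable signature
  genes (default τ = 1, strict concordance).

## A worked example

```r
library(pdmg)
report <- run_pipeline("pdmg_run", simulate = TRUE, seed = 1)
```

This simulates the three modalities from one planted truth (2000 genes, a
40-gene signature at 4-fold effect, 6v6 bulk samples, 2000 single-nucleus
cells over 5 donors per condition, 600 spatial cells with a 5.4% planted
consensus subpopulation), runs every stage, and writes a report directory.
At seed 1 the report contains:

```
$ n_cells                 : int 600
$ signature_size          : int 46
$ n_pd_microglia          : int 72
$ n_consensus             : int 3
$ consensus_percentage    : num 4.17
```

Reading: the consensus construction recovered a 46-gene signature (the 40
planted genes plus a handful of correlated false positives from the noisy
single-nucleus modality); among the 72 spatial cells that were annotated
as disease microglia, 3 followed the signature strictly — 4.17%, against
a planted rate of 5.4% (at 72 cells the binomial noise on that percentage
is large; the acceptance script below checks the same recovery at 653
cells, where it lands on the planted rate). The dominant gene was removed
before single-cell analysis exactly at its planted share:

```
  gene  fraction
1 GFAP 0.5999997
```

and the per-condition deconvolution averages show the disease bulk samples
dominated by the microglial profile, as planted:

```
        astrocyte endothelial microglia neuron oligodendrocyte
control     0.205       0.199     0.205  0.197           0.194
disease     0.173       0.164     0.339  0.159           0.165
```

`pdmg_run/` also holds `de_bulk.tsv`, `de_sn.tsv`, `signature.json`,
`props.csv`, the classified `cells.csv`, `class_summary.tsv`, and a
deterministic `report.json` (two runs at the same seed are
byte-identical).

A thin command-line wrapper over the same functions ships at
`inst/cli/pdmg.R` (`simulate`, `de`, `signature`, `deconvolve`, `spatial`,
`classify`, `run` subcommands).

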