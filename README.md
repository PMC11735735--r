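# hashclust

Clustering-based demultiplexing of single-cell hashtag counts.

Multiplexed single-cell experiments label every cell of a sample with a
unique oligo barcode (hashtag: HTO, LMO or CMO) before pooling. After
sequencing, each cell must be assigned back to its sample of origin from the
tag-by-cell count matrix — or flagged as a doublet (two samples in one
droplet) or a negative (no confident tag). Real hashing data carry two kinds
of technical noise that break naive top-tag assignment: tag-specific ambient
background and per-cell sequencing-depth variability.

`hashclust` demultiplexes by clustering cells in normalized tag space rather
than modeling each tag's count distribution:

1. **Normalize** the counts `r_ij` (tag `i`, cell `j`); the default is the
   per-cell centered log-ratio `n_ij = ln(r_ij / G_j + 1)` with `G_j` the
   (pseudocount-1) geometric mean of cell `j`'s tags, which treats each
   cell's tags as compositional and removes depth variability. Also
   available: per-tag CLR `ln(r_ij / G_i + 1)` (removes ambient bias),
   log-normalization `ln(r_ij 10^4 / S_j + 1)` and relative counts
   `r_ij 10^4 / S_j`.
2. **Cluster** cells with a shared-nearest-neighbor graph (Jaccard weights
   over Euclidean kNN neighborhoods, pruned at 1/15) partitioned by Louvain
   community detection.
3. **Call marker tags** per cluster by one-vs-rest Wilcoxon rank-sum tests:
   a marker must be detected in every cell of the cluster, have
   Bonferroni-adjusted p < 0.05, and exceed a log fold-change threshold.
   0 markers → Negative, 1 marker → that tag, ≥2 markers → Doublet.
4. **Calibrate** the logFC threshold so the achieved doublet fraction is
   closest to the expected doublet rate
   `8e-6 · n_cells · (n_tags − 1) / n_tags` (or a user-set rate); ties go to
   the smallest threshold.
5. **Vote**: the pipeline runs over a grid of k ∈ {5,…,30} and resolution
   ∈ {1,…,4}; each cell takes its modal label across runs, with the
   agreement fraction as a confidence score.

The package also ships the matching tag-count simulator (uniform own-tag
signal, multinomial cell-bound contamination, Poisson ambient background
with log-uniform tag levels) and the evaluation statistics used to benchmark
demultiplexers: per-tag/macro F-score, doublet-to-singlet misclassification,
per-tag AUCPR separability, and the two dataset noise metrics (baseline
expression variability, sequencing-depth variability).

## Worked example

```r
library(hashclust)

ds <- simulate_dataset(sim_config(n_tags = 5, cells_per_tag = 300, seed = 1))
res <- demux_ensemble(ds$matrix, k_grid = c(10, 20), resolution_grid = c(1, 2),
                      expected_rate = 0.1, seed = 1)
print(res)
evaluate_demux(res, ds$truth, ds$matrix)
```

```
demux_result: 1500 cells, 5 tags, 4 runs (clr_seq_depth)
expected doublet rate: 0.1000

    Tag1     Tag2     Tag3     Tag4     Tag5  Doublet Negative
     283      266      279      289      221       93       69
mean confidence: 0.964
evaluation_report
  average F-score: 0.9511
  doublet-to-singlet rate: 0.3533
  per-tag F: Tag1=0.958 Tag2=0.966 Tag3=0.973 Tag4=0.966 Tag5=0.892
  baseline expression variability: 0.4615
  sequencing depth variability: 6.31
```

The simulated pool has 1500 cells across 5 samples with 10% doublets, 2%
cell-bound contamination and an ambient background up to 100 reads/cell.
The ensemble assigns 89% of cells to a sample with mean vote confidence
0.96 and a macro F-score of 0.95 against ground truth. The doublet-to-
singlet rate of 0.35 reflects the known weak spot of clustering-based
doublet calling: doublets whose minor tag signal sits near the ambient
level are statistically close to singlets (the practical remedy is post hoc
RNA-based doublet filtering). `expected_rate = 0.1` is passed explicitly
because the generator's doublet rate is known by design; on real data the
default `"auto"` loading heuristic applies. `run_report(res)` shows each
run's chosen threshold and achieved doublet rate, and
`write_labels(res, "labels.csv")` serializes the assignment.

A thin command-line front end over the same functions is installed at
`inst/cli/hashclust.R` (subcommands `normalize`, `demux`, `simulate`,
`evaluate`).

## Acceptance script

`scripts/acceptance.R` regenerates the package's headline simulation
quantity from scratch with the installed package — it builds one default
noise-grid dataset (5 tags × 1000 cells/tag) and recomputes the ground-truth
doublet percentage — and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
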