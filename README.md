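# refstab

Selecting stable reference (housekeeping) genes for RT-qPCR normalization.

RT-qPCR expression measurements are only as reliable as the reference genes
they are normalized against, and supposedly invariant housekeeping genes
(Actin, GAPDH, tubulins, 18S rRNA, ...) routinely turn out to be
condition-dependent. `refstab` implements the standard validation workflow
for a candidate reference-gene panel measured across many samples:

- **Cq ingestion and QC** — long- or wide-format quantification-cycle (Cq)
  tables with technical replicates, sample metadata and per-assay
  characteristics; replicate-dispersion flags and a strict
  complete-matrix aggregation policy (drop, never impute).
- **Relative quantities** — `Q = E^(minCq − Cq)` per gene, with a fixed
  amplification base (default 2) or measured per-gene efficiencies;
  standard-curve efficiency estimation via `E = 10^(−1/slope)`.
- **geNorm** — the pairwise stability measure
  `M_j = mean_k SD_samples( log2 Q_j − log2 Q_k )`, stepwise exclusion of
  the least stable gene, normalization factors (geometric means), and the
  pairwise-variation curve `V_n = SD( log2 NF_n/NF_{n+1} )` with the 0.15
  cutoff rule for the optimal number of reference genes.
- **NormFinder** — the model-based estimator: fit
  `y_ij = α_i + β_j + ε_ij` on log quantities, estimate each gene's own
  error variance `σ̂²_i = max(0, g/(g−2) · (z_i − Σ z_k / (g(g−1))))` with
  `z_i = Σ_j r_ij²/(n−1)`, stability `ρ_i = √σ̂²_i`; a grouped variant adds
  a shrunken gene-by-group bias term.
- **Consensus** — top-k / bottom-2 agreement between the two rankings.
- **Relative quantification** — efficiency-corrected, multi-reference
  ratio-to-calibrator quantification of a target gene
  (`E_t^(minCq−Cq) / NF`, scaled so the calibrator condition is 1), with
  side-by-side comparison of normalizer choices.
- **Synthetic data** — a seeded replicate-level Cq generator with known
  per-gene instability, shared loading effects, group shifts and technical
  noise, including a ready-made 12-gene / 150-sample / 13-analysis-panel
  study design, so the whole pipeline is testable against ground truth.

## Worked example

A small synthetic panel (4 genes × 6 samples × 3 technical replicates)
ships with the package:

```r
library(refstab)

ds <- read_cq_long(system.file("extdata", "synthetic_cq_example.csv",
                               package = "refstab"))
qm <- relative_quantities(aggregate_replicates(ds))

rep <- stepwise_exclusion(qm)
rep
#> Stability report (genorm), 4 genes
#>   ranking (best -> worst): EF1a, GAPDH, Actin, TUA
#>   final pair EF1a + GAPDH, M = 0.155

pairwise_variation(qm, rep$ranking)
#> Pairwise-variation curve (cutoff 0.15):
#>  V2/3  V3/4
#> 0.141 0.174
#>   optimal number of reference genes: 2

nf <- normfinder_stability(log_quantities(qm))
nf
#> NormFinder stability (single group), 4 genes
#>   EF1a  GAPDH  Actin    TUA
#> 0.0000 0.2085 0.4028 0.6813
#>   variance clipped at 0 for: EF1a

compare_rankings(rep$ranking, rank_by_stability(nf), k = 2)
#> Ranking consensus (k = 2)
#>   top-k overlap: 2 of 2
#>   least-stable agreement: Actin, TUA
#>   best of b in top-k of a: TRUE
```

Reading: both algorithms agree that EF1a and GAPDH are the stable pair
(geNorm's final pair shares one M value, here 0.155 cycles of pairwise
log-ratio dispersion) and that Actin and TUA are the least stable. V2/3 =
0.141 < 0.15, so two reference genes suffice for this panel. The generator
indeed simulated EF1a/GAPDH with the smallest instability SDs and TUA with
the largest, so the recovered ordering matches the ground truth.

Standard-curve efficiency from a dilution series:

```r
sc <- read.csv(system.file("extdata", "synthetic_standard_curve.csv",
                           package = "refstab"))
efficiency_from_standard_curve(sc, gene_id = "GAPDH")
#> Standard curve (GAPDH)
#>   slope -3.4145, intercept 21.034, R^2 0.9998
#>   efficiency 1.963-fold per cycle
```

The full simulated study design (150 samples in nine experimental sets,
thirteen analysis panels) and the batch driver:

```r
pd <- longan_study_design(seed = 1)
m  <- aggregate_replicates(pd$dataset, meta = pd$meta, assays = pd$assays)
bundles <- run_all_sets(m, pd$set_filters)   # 13 per-panel result bundles
```

File-based pipeline drivers (`cmd_simulate()`, `cmd_rank()`,
`cmd_relquant()`) write JSON + CSV reports; a thin command-line wrapper
lives at `inst/cli/refstab.R`.

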