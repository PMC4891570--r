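---
title: "Reference-gene stability: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR quantifies a target transcript relative to one or more reference
genes assumed to be expressed at a constant level across all samples. When
that assumption fails — and it fails often, in a tissue- and
treatment-dependent way — the normalized profile inherits the reference
gene's drift and the biological conclusion can invert. Before a panel of
candidate reference genes is trusted, their stability must be measured on
the actual experimental material, separately for every experimental
condition, and the number of genes needed for a robust normalization
factor must be decided. `refstab` implements the two standard stability
estimators (the pairwise geNorm measure and the model-based NormFinder
estimator), the pairwise-variation rule for the gene count, their
consensus, and the downstream efficiency-corrected quantification that the
whole exercise exists to protect.

## From Cq to relative quantities

The instrument reports a quantification cycle Cq (equivalently Cp) per
well; one cycle difference corresponds to one doubling of template under
perfect amplification. Technical replicates are collapsed first —
arithmetic mean of Cq by default, the de-facto qPCR convention (median is
offered for outlier robustness). The replicate-SD QC threshold defaults to
0.5 cycles, a common laboratory heuristic for flagging pipetting problems;
it is configurable and report-only.

Both stability algorithms consume relative quantities per gene:

    Q[g, s] = E_g ^ (minCq_g − Cq[g, s])

so the most abundant sample of each gene gets Q = 1 exactly and all other
samples fall in (0, 1]. The default efficiency is the fixed base
E = 2 for every gene, matching the conventional transform; per-gene
measured efficiencies (from dilution-series standard curves, via
E = 10^(−1/slope)) are supported as a sensitivity mode and for target-gene
quantification, where the efficiency correction genuinely matters. The
per-gene minimum is taken within the analysed sample subset, not globally:
rescaling Q per gene is provably irrelevant to both stability measures (a
per-gene Cq shift cancels in log-ratios and in the two-way fit), so the
choice is cosmetic, and subset-local scaling keeps every subset's Q
self-contained.

Missing wells are never imputed. Both algorithms require complete
gene × sample matrices, and imputation would manufacture exactly the kind
of low-variance signal the estimators are hunting for; the policy is to
drop incomplete samples (recorded in the QC report) and to refuse genes
missing in more than a configurable fraction of samples.

## geNorm

For genes j and k, the pairwise variation is the sample standard deviation
(n − 1 denominator) of log2(Q_j / Q_k) across samples; gene j's stability
is the mean of this over all partners:

    M_j = mean_{k ≠ j} SD_s( log2 Q_js − log2 Q_ks )

Two genes that are co-regulated or both stable have a near-constant ratio
and small M. The ranking is produced by stepwise exclusion: compute M on
the remaining set, drop the gene with the largest M, repeat until two
genes remain. The final pair shares one M value (for two genes the measure
degenerates to the SD of their single log-ratio and cannot separate them);
it is reported as a tied best pair, with display order given by the
deterministic gene ordering. Ties at an exclusion step are resolved by
excluding the gene latest in the gene ordering — an arbitrary but
documented and reproducible rule.

The recommended number of reference genes comes from the
pairwise-variation curve. With NF_n the per-sample geometric mean of the
top-n genes' quantities,

    V_n = SD_s( log2( NF_n[s] / NF_{n+1}[s] ) )

small V_n means the (n+1)-th gene barely changes the normalization factor.
The optimal count is the smallest n with V_n below the cutoff, 0.15 by
default — the conventional threshold, explicitly adjustable since it is a
heuristic, not a statistical test. When no V falls below the cutoff no
count qualifies; the package returns a sentinel (`NA`) and the
accompanying advisory is the pragmatic fallback of using at least the
three most stable genes. The exclusion trace stores the full M vector at
every step, so either the average-M-of-remaining trajectory or per-gene
trajectories can be plotted from the same object.

## NormFinder

The model-based estimator assumes additive log-scale expression,

    y_ij = α_i + β_j + ε_ij,   Var(ε_ij) = σ²_i,

with gene effects α (abundance) and sample effects β (loading, RT
efficiency) removed by double centering. With residuals
r_ij = y_ij − ȳ_i· − ȳ_·j + ȳ_·· and z_i = Σ_j r_ij² / (n − 1), the
gene-specific variance estimate is

    σ̂²_i = max(0, g/(g−2) · ( z_i − Σ_k z_k / (g (g−1)) )),

and the stability value is ρ_i = σ̂_i. The correction factor accounts for
each gene's own contribution to the common fit; it is undefined for g ≤ 2,
which the package reports as an explicit estimator-degeneracy error.
Negative raw estimates are clipped at zero and the affected genes are
listed in the result, since a clipped zero means "indistinguishable from
perfectly stable at this sample size", not "exactly stable".

In grouped mode (treatment arms, tissues, timepoints) a gene can be
precisely stable within groups yet shifted between them — the worst kind
of reference gene. Per group, intragroup variances are estimated as above
restricted to the group; the gene-by-group interaction d_gi is the group
mean of the full-fit residuals; it is shrunk toward zero by the factor
`var_genes(d) / (var_genes(d) + σ̂²_gi / n_g)` (a zero denominator yields
d̃ = 0), and the stability value averages `|d̃_gi| + sqrt(σ̂²_gi / n_g)`
over groups. Because no printed constants exist to copy for these
estimators, they are validated by Monte-Carlo oracles: the mean estimated
σ̂ regressed on the true simulated σ has slope within [0.9, 1.1] at
g = 6, n = 500, and a 1.0 log2-unit between-group shift on one gene is
flagged least stable in ≥ 95% of runs at 20 samples per group. Single-group
mode is the default, since a stability value per gene per sample set is
the common reporting unit and grouping metadata is often absent.

Input is log2 relative quantities; a direct matrix path (e.g. negated Cq)
gives identical results because per-gene constants vanish in the centering
— a property the tests assert rather than assume.

## Consensus

The two algorithms measure different things (pairwise co-stability vs
model variance) and their full orderings rarely coincide. The consensus
report therefore compares: the overlap of the top-k prefixes (k defaulting
to half the panel), agreement of the bottom-2 (least stable) genes, and
whether the model-based best gene appears in the pairwise top-k. These are
the criteria under which the two methods corroborate a panel choice.

## Efficiency-corrected target quantification

A validated reference set feeds the quantification of the actual gene of
interest. The package uses the efficiency-corrected ratio-to-calibrator
model: the raw per-sample ratio is

    r_s = E_t ^ (minCq_t − Cq_t,s) / NF_s

and reported values are r_s divided by the mean r over the calibrator
samples (or calibrator condition), so the calibrator averages to exactly 1.
With all efficiencies at 2 and a single reference this reduces
algebraically to the classic 2^−ΔΔCq, which the tests verify symbolically
on random inputs. Biological replicates are aggregated as mean ± SD per
condition after technical replicates were collapsed upstream.
`compare_normalizers()` runs several candidate reference sets under
identical calibrator scaling, which is how the cost of a bad normalizer is
demonstrated: a reference whose quantity drifts downward under treatment
inflates the apparent target fold change proportionally.

## The synthetic-data generator

The generator produces replicate-level Cq data under the model

    Cq[g, s, r] = baseline[g] + sample_effect[s] + group_shift[g, grp(s)]
                  + gene_noise[g, s] + tech_noise[g, s, r]

with independent zero-mean normal noise throughout. Additive normality on
the Cq scale is the natural choice: Cq already lives in log-fluorescence
cycle space, where technical variation is approximately homoscedastic.
The components map one-to-one onto what the estimators must separate: the
shared per-sample effect emulates loading/RT variation and must cancel in
both algorithms (asserted exactly, by reusing one seed with two
sample-effect magnitudes); the per-gene noise SD is the instability that
defines the true stability order; group shifts create
treatment-responsive genes for grouped-mode and normalizer-distortion
experiments; technical noise shrinks by replicate averaging.

Defaults are chosen to be realistic for a plant reference-gene panel:
baselines spread over 15–30 cycles (the observed panel range being roughly
11–35), instability SDs graded 0.05–0.6 cycles (clearly stable to clearly
unstable), loading SD 1.0 cycle, technical SD 0.15 cycles, three technical
replicates. `longan_study_design()` instantiates the full study bookkeeping this
package's validation scenario emulates: 12 named genes whose baselines
echo the panel's observed abundance ordering (18S rRNA most abundant,
Fe-SOD least) and whose instability grading makes the tubulins the
noisiest and GAPDH/EF-1a the most stable, across 150 samples in nine
experimental sets (36 + 36 + 18 + 9 + 9 + 9 + 9 + 12 + 12) expanding to
thirteen analysis panels, plus the measured assay table (efficiencies
1.914–2.072, amplicon lengths, Tm).

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: co-regulation between reference genes
(geNorm's known blind spot, since a co-regulated pair gets a flattering
M), plate/position effects and inter-run batch structure, heteroscedastic
noise at very high Cq near the detection limit, and non-normal outliers
from failed wells beyond what the replicate-SD QC flags. Results on real
panels should be read with those caveats.

## Numerical and design notes

- Log base 2 everywhere; sample SD uses the n − 1 denominator, matching
  the original tools' conventions so oracles agree to machine precision.
- All orderings (genes, samples, tie-breaks) are lexicographic in the C
  locale unless explicit orders are given, making every output
  deterministic; all simulation randomness flows through one integer seed.
- The per-gene maximum of Q is exactly 1 by construction (the exponent is
  exactly zero at the minimum-Cq sample), so the invariant holds without
  tolerance.
- Validation problem sizes were fixed up front at the scale of the
  emulated study: 500 random matrices for oracle equivalence, 200
  simulations for ranking recovery (12 genes × 36 samples, graded
  0.05–0.6 SDs), 100 replicates at n = 500 for variance recovery, 200
  runs at n_g = 20 for grouped spike detection, 100 simulations for
  4-fold spike recovery. The whole suite runs in well under a minute.
- Known limitations: no inter-run calibration, no confidence intervals on
  M or ρ, no RDML/instrument-export parsing, no additional ranking
  methods (BestKeeper, ΔCt, RefFinder-style meta-ranking); the consensus
  layer is deliberately limited to the two implemented algorithms.
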