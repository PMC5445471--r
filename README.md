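# quantdss

Standard-curve qPCR quantification with a quality-control decision
support system.

## What problem this solves, and for whom

Quantitative PCR gives you, per well, a quantification cycle (Cq) — the
cycle at which amplification fluorescence crosses a threshold. Turning a
plate of Cq values into *reliable* relative copy numbers requires more
than back-calculation: extraction yields differ between samples,
replicates near the assay's limits scatter stochastically, some wells
never amplify, and inhibitors in difficult matrices (plant, food,
environmental samples) distort individual samples' amplification
efficiency so badly that their numbers are meaningless. Most analysis
tools compute values without telling you which ones to distrust.

`quantdss` is for researchers doing standard-curve-based relative
quantification — gene expression, pathogen load, GMO content — who want
every reported number to have survived an explicit, tunable quality-control
decision tree, and every modified or refused number to carry a warning
explaining why.

## The model

Over the quantifiable range, Cq is linear in log quantity:

    Cq = b + m * log10(Q),        m < 0

The standard curve (ordinary least squares over a serial dilution of
standards) gives slope `m`, intercept `b`, and the amplification
efficiency `E = (10^(-1/m) - 1) * 100%` (100% = doubling per cycle,
`m ≈ -3.32`). Sample copy numbers invert the line:
`Q = 10^((Cq - b)/m)`; replicates are averaged (CV tracked), corrected by
the dilution's relative template quantity, and normalized to the average
of the reference genes, each scaled to the first-imported one.

Every sample × target cell then passes a hierarchical decision tree:

1. **Extraction control** — all reference genes above the Cq ceiling
   (default 34) → no result.
2. **Limit of detection** — nothing amplified → a small value is imputed
   (below every LOQ imputation, never zero).
3. **Limit of quantification** — dilution 1 beyond the LOQ Cq, replicate
   CV > 30%, or replicate dropout → LOQ-imputed; only dilution 2 under →
   dilution 1 alone carries the result.
4. **Per-sample efficiency** (two-dilution mode) — the sample's own slope
   `(Cq2 - Cq1)/(log10 q2 - log10 q1)` outside `[-4.5, -2.5]` or more
   than 1.0 from the curve's slope (inhibition/over-amplification
   signature) → no result.

All thresholds are settings (`qc_settings()`); a classic ΔΔCq comparator
(`ddcq_quantify()`) is included for method comparison.

## Worked example

A synthetic 12-sample experiment (one target, two reference genes, two
ten-fold dilutions, 0.1-cycle noise) covering the regimes the tree must
separate:

```r
library(quantdss)
cfg <- sim_mixed_config(n_samples = 12, cq_noise_sd = 0.1, seed = 7)
sim <- simulate_experiment(cfg)
res <- quantify_experiment(sim$experiment, sim$standards, cfg$qc)
res$curves$T
#> Standard curve: Cq = 20.0000 -3.3219 * log10(quantity)
#>   efficiency 100.0%, R^2 1.0000, 10 point(s), Cq(LOQ) 33.29
res
#> Quantification result 'simulated': 12 samples x 1 target gene(s), mode two_dilution
#>
#>          IMPUTED_LOD          IMPUTED_LOQ NO_RESULT_EFFICIENCY
#>                    1                    1                    1
#> NO_RESULT_EXTRACTION                   OK
#>                    1                    8

m <- export_matrix(res)
cbind(m$values, warnings = m$warnings$T)
#>    sample         T                                               warnings
#> 1     S01 1.008e+00                                                     OK
#> ...
#> 9     S09 2.082e-05      IMPUTED_LOD;ALL_REPLICATES_UNDETECTED_IMPUTED_LOD
#> 10    S10 9.934e-05                 IMPUTED_LOQ;DIL1_UNDER_LOQ_CQ_OVER_LOQ
#> 11    S11        NA NO_RESULT_EFFICIENCY;SAMPLE_SLOPE_OUT_OF_RANGE(-1.273)
#> 12    S12        NA    NO_RESULT_EXTRACTION;EXTRACTION_FAIL_ALL_REFERENCES
```

Reading the output: S01–S08 are normally quantified normalized copy
numbers. S09 never amplified, so it gets a small LOD-imputed value (and
says so). S10's first dilution sits beyond the LOQ Cq of 33.29, so its
value is imputed at the LOQ. S11 is PCR-inhibited — its own two-dilution
slope is −1.27 against a curve slope of −3.32 — so no number is reported
rather than a wrong one. S12's reference genes all failed the extraction
control.

Real data enters the same way from tab-delimited tables
(`parse_gene_table()`, `parse_standard_table()`, header
`sample dilution replicate cq rel_quantity` resp. `quantity cq`), is
structure-checked across genes with `check_consistency()`, and is written
out with `write_result()` (value matrix, warnings matrix, per-gene
intermediate-value tables). A thin command-line front end with
`validate` / `run` / `export-matrix` / `simulate` subcommands lives at
`inst/cli/quantdss.R`.

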