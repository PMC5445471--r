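---
title: "Standard-curve qPCR quantification with QC decision support: methods"
author: "quantdss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-curve qPCR quantification with QC decision support: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantdss)
```

## The quantification model

qPCR measures a template quantity through the quantification cycle $C_q$,
the cycle at which amplification fluorescence first crosses a threshold.
Over the quantifiable range, $C_q$ is linear in the decadic logarithm of
the initial template quantity $Q$:

$$C_q = b + m \log_{10} Q,$$

with slope $m < 0$ and intercept $b$ (the $C_q$ at $Q = 1$). `quantdss`
fits this line by ordinary least squares to a serially diluted standard
(`fit_standard_curve()`), keeping replicate standard wells as individual
points so that replicate scatter shows up in $R^2$. The amplification
efficiency — the fraction of molecules copied per cycle — follows from the
slope as

$$E = \left(10^{-1/m} - 1\right) \times 100\%,$$

so $m = -1/\log_{10} 2 \approx -3.32$ is exactly $100\%$ (doubling per
cycle). Sample copy numbers invert the line:
$\hat{Q} = 10^{(C_q - b)/m}$ (`copy_number_from_cq()`).

Per (sample, dilution), replicate copy numbers are averaged and their
coefficient of variation computed — on copy numbers, not on $C_q$, with
the $n-1$ standard deviation — and the mean is divided by the dilution's
relative template quantity, putting all dilutions on one scale
(`dilution_quants()`).

### Reference-gene normalization

Targets are normalized to one or several reference genes. To give each
reference gene equal weight, and to keep a sample quantifiable when one
reference gene is dropped by QC, every reference gene $k$ is first rescaled
to the level of the first-imported one by the factor

$$f_k = \frac{\overline{x}_{1}}{\overline{x}_{k}},$$

the ratio of across-sample means, computed for each dilution separately
over the samples where both genes have a value. The sample's reference
average is the arithmetic mean of its available scaled values; the
normalized target value is the target's dilution-corrected copy number
divided by that average, and the final two-dilution value is the unweighted
mean of the two per-dilution normalized values. Swapping the import order
of reference genes rescales every sample by one common factor, so
between-sample ratios are invariant (tested to $10^{-9}$).

Two open design points were resolved as follows and are deliberate package
choices:

* **Which samples enter the scale factor.** Factors are computed over all
  samples where the gene has a value, including samples later refused by
  QC. A factor is a property of the gene pair, not of a sample; letting a
  sample's QC verdict change every other sample's reference average would
  make results non-local and order-dependent. QC only removes a gene from
  the *affected sample's* average.
* **Which reference average feeds the LOQ/LOD imputations.** The
  dilution-1 reference average (falling back to dilution 2 if needed),
  matching the simple-calculation path that the imputation mimics.

## The decision support system

Every sample × target-gene cell passes a hierarchical decision tree
(`decide_final()`); each stage either passes the cell on, modifies the
result (imputation), or refuses it, always leaving an ordered warning
trail:

1. **Extraction control.** A reference gene fails for a sample when its
   dilution-1 mean $C_q$ exceeds `cq_extc` (default 34 cycles) or nothing
   amplified; a failing gene is dropped from the sample's averaging.
   Only if *every* reference gene fails is the target refused
   (`NO_RESULT_EXTRACTION`). The dilution-1 mean is used because the
   least-diluted reaction is the most sensitive detector of a failed
   extraction.
2. **Limit of detection.** If every target well at every dilution is
   undetected, the result is imputed as the LOQ imputation divided by
   `lod_divisor` (default 5): strictly positive and strictly below every
   LOQ-imputed value, so downstream statistics need no separate
   missing-data handling (`IMPUTED_LOD`). References are never
   LOD-imputed — they must sit well above the LOQ to pass stage 1.
3. **Limit of quantification.** A dilution is "under the LOQ" when its
   mean $C_q$ exceeds the gene's `cq_loq`, its replicate CV exceeds
   `cv_max_percent` (default 30%), or some replicates dropped out
   (partial dropout is read as sub-LOQ pipetting stochasticity). If
   dilution 1 is under, the cell gets the LOQ imputation
   $\hat{Q}(C_{q,\mathrm{LOQ}}) / \mathrm{refavg}$ (`IMPUTED_LOQ`); if
   only dilution 2 is under, dilution 1 alone carries the result
   (`OK_DIL1_ONLY`) and stage 4 is skipped, because a sub-LOQ dilution 2
   would confound the sample slope.
4. **Per-sample efficiency control** (two-dilution mode only). The
   sample's own slope,
   $(C_{q,2} - C_{q,1}) / (\log_{10} q_2 - \log_{10} q_1)$, must lie in
   `[slope_min, slope_max]` (defaults $[-4.5, -2.5]$, roughly 67–150%
   efficiency) and within `slope_diff_max` (default 1.0) of the standard
   curve's slope; otherwise the cell is refused
   (`NO_RESULT_EFFICIENCY`). The control is applied independently to
   reference genes: a failing reference is dropped from that sample's
   average, and if all fail the sample's targets are refused.

`cq_loq` defaults to the mean $C_q$ of the most-diluted included standard
level — beyond it, quantification is unverified by the standards — and can
be overridden globally or per gene. The default slope window and
`slope_diff_max` are intentionally loose, aimed at reliably resolving
two-fold differences; applications needing smaller measurement uncertainty
should tighten them (tightening never upgrades a refused or imputed cell
to OK; this monotonicity is property-tested).

The one-dilution ("simple") tree is the same minus stage 4 and the
dilution-2 branch of stage 3.

### The ΔΔCq comparator

`ddcq_quantify()` implements the classic comparative-cycle method,
$2^{-\Delta\Delta C_q}$, assuming equal 100% efficiencies. It exists for
method comparison, not production use: at exactly 100% efficiency for all
assays the two routes agree to numerical precision (tested to $10^{-9}$),
and they drift apart as efficiencies leave 100%.

## What the simulator emulates

`simulate_experiment()` generates experiments from known truth: each
assay has a true line $(m, b)$; standards are produced noise-free from it
(so curve error never confounds decision-tree tests); sample wells get
Gaussian noise on the $C_q$ scale (log-normal on copies), which matches the
replicate behaviour of real instruments well; wells whose *expected* $C_q$
exceeds `lod_cq_cutoff` go undetected, making detection deterministic and
the intended status of every cell derivable in closed form. PCR inhibition
is an additive $C_q$ offset on dilution-1 wells, which reproduces the
reversed-dilution signature of inhibited samples (a +2-cycle offset moves a
$-3.32$ sample slope to $-1.32$).

It does **not** emulate: stochastic single-molecule detection near the
LOD (real sub-LOQ wells drop out probabilistically, not at a sharp
threshold), plate-position effects, inter-plate variation, fluorescence
curve shapes, or genomic-DNA background. Consequently, a passing test
suite shows the *calculation and decision logic* are right under realistic
noise; it does not validate assay design or qualitative pre-QC, which
remain the user's wet-lab responsibility.

Canned scenarios:

* `sim_mixed_config()` — the validation workhorse: 20 samples (14
  quantifiable across 2.5 logs, 2 sub-LOD, 2 sub-LOQ, 1 target-inhibited,
  1 failed extraction), 2 replicates, 2 ten-fold dilutions, margins of
  ≥1.3 cycles (≥18 standard errors at 0.1-cycle noise) to every
  threshold so intended statuses are unambiguous.
* `sim_expression_study()` — a synthetic two-target expression study with
  efficiencies a few percent off 100% (slopes $-3.45$ to $-3.25$), two
  stable references, a shared per-sample extraction yield and 0.15-cycle
  noise, for comparing the standard-curve and ΔΔCq routes.
* `sim_gmo_inhibition()` — a synthetic GMO-diagnostics sample (true 33%
  transgene content) with two DNA isolations whose reference assay is
  inhibited harder than the transgene assay: the uncontrolled per-dilution
  %GMO estimates scatter from ~32% to ~810%, while the decision tree
  refuses the sample through the reference-efficiency branch.
* `sim_branch_config()` — one fixture per decision-tree branch, used to
  check the tree exhaustively (120 axis combinations) against a
  hand-transcribed truth table. Some axis combinations are physically
  unrealizable (dilution 2 can never be over the LOQ while dilution 1 is
  under it, since it always has the higher $C_q$); the tree never consults
  those axes on the affected paths, and the CV-based LOQ trigger —
  unreachable in a deterministic simulation — is unit-tested directly.

## Numerical choices and degenerate inputs

* Curve fitting requires ≥2 included points over ≥2 distinct quantities;
  anything less is an explicit error, not a silent NA.
* A non-negative fitted slope yields a warning-carrying efficiency (the
  formula is still evaluated); a zero slope is an error.
* Undetected $C_q$ cells accept the common instrument encodings (empty,
  `NA`, `Undetermined`, `999`) and normalize to one sentinel.
* Replicate CV is undefined (NA) below two detected replicates; the
  partial-dropout LOQ trigger covers that case instead.
* Serialization writes numbers at 17 significant digits so
  parse(serialize(x)) is bit-exact.
* Sample output order is first-appearance order in the first imported
  assay; decimal separator is the dot, tabs delimit.
* Problem sizes used in the shipped validation: 20-sample scenarios, 200
  Monte-Carlo replicates at 0.1-cycle noise, 1000-instance oracle and
  ordering sweeps — large enough for stable estimates while keeping the
  whole suite around a minute.

## Known limitations

* No robust (outlier-resistant) regression for the standard curve;
  outlier standard wells are flagged (`flag_standard_outliers()`) for
  user exclusion, never removed automatically.
* No efficiency-corrected ΔΔCq variants, no geometric-mean multi-reference
  normalization, no inter-plate calibrators, no reference-gene selection
  (GeNorm-style) — validated references are assumed.
* Qualitative pre-QC (amplification-curve inspection, no-template and
  gDNA controls, melt curves) must happen before import.
* The LOD imputation can create false "positives" where a target is truly
  absent; for presence/absence questions, export without imputed values
  (the warnings matrix marks every imputed cell).
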