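---
title: "TF activity profiling: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TF activity profiling: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `tfap`, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the problem was genuinely open. It
states no empirical claim that the test suite does not itself compute.

## The measurement model

A reporter construct for TF *t* expresses a reporter transcript from a
minimal promoter carrying *t*'s binding sites and a reference transcript
from a constitutive PGK promoter. Raw activity is the ratio

\[ a_{it} = \frac{\text{reporter copies}_{it}}{\text{reference copies}_{it}}, \]

with both copy numbers obtained by absolute qPCR against standard dilution
series (`fit_standard_curve()`: OLS of Cq on log10 copies; efficiency
\(E = 10^{-1/\text{slope}} - 1\), the standard qPCR convention — the source
protocol does not state one). The ratio convention is direction-free: for
repressive TFs (REST/NRSF), increased activity is still an elevation of the
reporter:reference ratio.

Each animal carries at most **six** constructs (a battery). Batteries are
fixed panels of TFs cycled across animals within every group, so a panel of
30 TFs is covered by five experiments; activities are normalized to the
mean of control animals **within the same experiment and TF**
(`normalize_to_controls()`), which removes construct- and batch-scale
effects and makes multi-experiment pooling legitimate. The per-stratum
control mean of 1 is an enforced invariant.

The group-level summary (`group_log2fc()`) is a "corrected" mean: the mean
of per-animal log2 normalized activities in the contrast group minus the
same mean in the reference group, with the SEM from the contrast group
alone. The correction term is ~0 after control normalization but makes the
contrast exact for arbitrary reference groups; whether the original
figure's error bars propagate control uncertainty is unstated, and we chose
not to propagate it.

## Behavior

SI-rate is the ratio of interaction-zone times between the target-present
and target-absent phases. The protocol text literally defines the
empty:occupied ratio, but the susceptible cutoff (SI < 1) and field
convention imply occupied:empty; `si_rate()` defaults to
`time_with_mouse / time_no_mouse` with a `direction` switch (the
discrepancy is deliberate and documented). Rules, all exact:
outliers are SI > 4 (strictly; 4.0 is retained), susceptible is SI < 1,
resilient SI ≥ 1, and time courses divide by the day-matched control mean.
Effect sizes use Hedge's *g* (pooled-SD *d* times \(J = 1 - 3/(4N-9)\)).
The recovery-proportion test is the exact two-sided binomial
(minimum-likelihood definition — unspecified in the source, chosen to match
`binom.test`) against the vehicle proportion, Holm-corrected; "not
exhibiting depressive symptoms" defaults to normalized SI ≥ 1 and is
configurable.

## Transcriptome and regulons

Counts become TPM (within-sample; no cross-condition length
renormalization). Differential expression uses Welch's *t* on
log2(TPM + 1) — the transform is not stated in the source; pseudocount 1 is
the package default — with fold change computed on the linear scale and BH
q-values reported alongside. The DEG rule is *p* < 0.05 and FC > 2 or
FC < 0.5 on the **raw** p-value by default (`use_q = TRUE` switches to BH),
because that is the printed rule even though both appear in the methods.

Degenerate genes (zero variance in both groups) are flagged; they get
*p* = 1 when the group means are equal and *p* = 0 when they differ. The
asymmetry matters only on noiseless data, where every gene is degenerate:
mean-equal genes are unambiguous nulls and mean-different genes carry
unambiguous signal, and this convention is the only one under which
noiseless DEG recovery can be exact.

Regulons are predicted by scanning promoter windows (default −1000/+200 bp
around the TSS — the source leaves the window to supplementary methods;
ours is the common convention and configurable) with log2-odds PWMs
(pseudocount 0.01 per cell, uniform background by default, both strands,
`N` scores −∞). The default threshold is 80% of each motif's maximum
achievable score; absolute-bits thresholds are available. Membership is a
set, so palindromic double hits count once. Regulon size is monotone
nonincreasing in the threshold by construction.

## Integration and driver ranking

For each TF, the activity log2FC is paired with the unweighted mean log2FC
of its predicted targets ("average expression changes"; a score-weighted
mean is optional), plus upper-tail hypergeometric DEG enrichment, a
two-sided rank-sum shift test of |log2FC| (regulon vs background; exact
when tie-free and n + m ≤ 30, else normal approximation with tie
correction and no continuity correction), and a two-sided F variance test
for contrast-broadening comparisons.

The driver ranking criterion is **not** published; our declared choice is
`|activity_log2FC| × |mean_target_log2FC|` times a sign-concordance
multiplier (1 when the downstream shift agrees with the TF's declared
activator/repressor mode, 0.25 otherwise), ties broken by enrichment p then
name. It is deliberately simple and transparent; on the reference synthetic
scenario it places both true drivers in the top 2 in ≥ 90% of seeded
replicates (acceptance criterion 1).

The Dunnett many-to-one comparison is computed by seeded Monte Carlo of the
joint null max-|t| distribution with the control draw shared across
comparisons (unit normal samples at the observed group sizes; Welch *t* is
treated as pivotal). The MC adjusted p is capped at the Bonferroni bound
`min(1, m·p)`, a valid upper bound that also makes the bound exact rather
than within-MC-error. Exact multivariate-t quadrature was rejected as
unnecessary at this scale; the MC path is auditable and seeded.

## The synthetic world

The generator emulates the study's generative structure with these stated
defaults: 30 TFs, 2 drivers with +0.5 log2 activity in the non-control
group, regulons of 30 genes with unit weight, 10 animals/group, batteries
of 6, expression noise SD 0.25 (log2), reporter noise SD 0.1 (log2,
multiplicative lognormal — transcript ratios are positive and
ratio-scaled), behavioral coupling −0.5 per driver with SI noise SD 0.15,
uniform promoter background with one implanted consensus site per true
target. Reporter noise, battery assignment, and behavioral noise are not
stated in the source; these values are declared once as what we consider
realistic for qPCR ratio assays and SI tests at this cohort size, and are
not revisited.

Structural choices worth knowing:

- **Driver regulons are disjoint**, and non-driver regulons are drawn from
  the unshifted gene pool. This makes the noiseless identities exact (each
  driver's mean target shift equals its activity shift; non-drivers' are
  zero). Real regulons overlap; a green driver-recovery test therefore
  does not establish robustness to shared targets.
- **One root seed** fans out to per-component child seeds
  (`child_seed()`: `(seed + 7919·offset) mod 2147483299`), so enlarging one
  component never perturbs another.
- `simulate_expression()` returns both rounded counts (the pipeline
  channel) and the unrounded linear matrix. Rounding and TPM library-size
  renormalization each perturb fold changes at the last decimal, so exact
  (< 1e−9) noiseless identity checks run on the unrounded channel with
  pseudocount 0; the counts/TPM channel is what every realistic analysis
  uses.
- The generator does **not** simulate read-level sequencing, qPCR
  amplification kinetics, plate effects, regulon weight heterogeneity, or
  cell-type mixtures; green tests say nothing about those.

## Numerical conventions

All tests are two-sided. BH and Holm are implemented closed-form and
checked against `p.adjust` to 1e−10; Welch/Pearson/F statistics likewise
against their `stats` references; hypergeometric and small-sample rank-sum
p-values against exhaustive enumeration. Ties in the per-cell high/low
rule classify as low. BED coordinates are 0-based half-open with mandatory
strand; promoter windows clip at contig bounds with a warning. Copies below
one template are allowed with a warning. The statistical calibration
checks (type-I error of the shift and variance tests, Dunnett family-wise
error) run at fixed seeds inside 3 binomial standard errors of the nominal
5% level.

## Known limitations

- The TFAP pools multi-experiment measurements after control normalization
  only; no further batch correction is attempted (unequal batteries beyond
  that are not modeled).
- The regulon scanner is promoter-proximal; distal enhancers and
  conservation weighting are out of scope.
- The joint activity–behavior mode reports the multiple correlation from a
  linear fit; it is descriptive, not causal.
- qPCR replicate handling and melt-curve QC are not modeled.
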