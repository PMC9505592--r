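---
title: "Validating reward-pathway risk alleles by case-control meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating reward-pathway risk alleles by case-control meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsmeta)
```

## The problem

Candidate-gene association studies of alcohol use disorder (AUD) and
related reward-deficiency phenotypes are numerous, small, and
heterogeneous: different ethnicities, diagnostic criteria, genotyping
platforms, and control-screening practices. Any claim that a particular
risk allele (say, the DRD2 Taq1A A1 allele) elevates AUD risk must
therefore rest on meta-analysis: per-study effect estimates, a pooled
estimate that acknowledges between-study heterogeneity, diagnostics for
the publication bias endemic to small-study literatures, and finally a
translation of the pooled odds ratio into a change in absolute risk that a
clinician can use.

`rdsmeta` implements that full chain for allele-level 2x2 case-control
tables, plus a panel-scoring stage for multi-allele risk indices, plus a
synthetic-data generator with known ground truth. The generator is not an
afterthought: the primary literatures behind panels of this kind (275+
studies) are not redistributable, so the pipeline's correctness is
established on simulated literatures whose true odds ratio, heterogeneity
and suppression mechanism are known exactly.

## Per-study statistics

Each study contributes a 2x2 allele-count table: risk/other allele counts
in cases and controls (carrier-based tables are handled identically; the
distinction is a labelling concern kept in metadata). The odds ratio is
the cross-product ratio; its log-scale standard error is the square root
of the sum of reciprocal cells. When any cell is zero the
Haldane-Anscombe correction adds 0.5 to all four cells; this is applied
per study, flagged in the output, and logged by the pipeline. A table
whose risk or other column is empty in *both* arms carries no information
about association and is excluded -- with a logged warning, never
silently.

Supporting tests follow the same conventions as mainstream
implementations so that oracles agree: Pearson chi-squared without
continuity correction; Fisher's exact test two-sided by the
point-probability rule (summing hypergeometric probabilities no larger
than the observed table's); Wilcoxon rank-sum with mid-ranks for ties,
exact enumeration up to a combined n of 10 and a tie-corrected normal
approximation (no continuity correction) beyond.

Hardy-Weinberg equilibrium is assessed per study arm when genotype counts
are available, by the chi-squared goodness-of-fit test against
(p^2, 2pq, q^2). Because the chi-squared approximation is
anti-conservative when a genotype class is sparse, the p-value switches to
the exact conditional test on the heterozygote count whenever an expected
genotype count falls below 5. HWE deviation *flags* a study (deviation in
controls often signals genotyping error) but does not auto-exclude it:
exclusion policy differs across meta-analytic practice, and silent
exclusion is the failure mode this pipeline is designed to avoid.
Monomorphic samples are reported as undefined rather than failing.

## Pooling

Two fixed-effects estimators are provided. Inverse-variance pooling
weights each log OR by `1/SE^2` and is the natural choice when only
estimate-level data are available. The Mantel-Haenszel estimator works
directly on the count tables, is robust to sparse cells without
per-stratum corrections, and is the pipeline default for fixed-effects
pooling of count-level input; its log-scale variance uses the
Robins-Breslow-Greenland estimator, valid in both the sparse-data and
large-stratum limits.

The random-effects model is DerSimonian-Laird exactly: Cochran's Q with
fixed-effects weights, the moment estimator
`tau2 = max(0, (Q - (k-1)) / (S1 - S2/S1))`, and re-weighting by
`1/(SE_i^2 + tau2)`. When Q does not exceed its degrees of freedom the
estimator truncates to zero and the random-effects result coincides,
bit for bit, with the inverse-variance fixed-effects result -- a property
the test suite asserts literally. No REML or Paule-Mandel alternatives are
offered; the moment estimator is the method this pipeline validates.

**Model selection.** The headline model per gene is chosen by the
conventional heterogeneity rule: random effects when the Q-test p-value
falls below a threshold (default 0.10, the customary level for the
low-powered Q test), fixed effects otherwise. I-squared
(`max(0, 1 - df/Q)`, clamped to [0, 1]) is reported alongside as the
proportion of variation attributable to heterogeneity. Accounts of this
procedure sometimes state I-squared-based rules with inconsistent
directionality; this package deliberately keys the decision to the Q-test
p-value, with the threshold configurable, and reports both quantities so
any alternative rule can be applied downstream.

Significance of the pooled log OR uses the standard Z-test; when several
polymorphisms are analysed in one run the Bonferroni correction is applied
with m defaulting to the number of polymorphisms (configurable).
Leave-one-out sensitivity re-pools with each study omitted in turn.

## Publication-bias diagnostics

- **Egger regression**: OLS of the standardized effect (`log OR / SE`) on
  precision (`1/SE`); under funnel symmetry the line passes through the
  origin, and the intercept is tested with t on k-2 degrees of freedom.
- **Begg-Mazumdar rank correlation**: each study's deviation from the
  fixed-effects pooled estimate is standardized by its variance-stabilized
  standard error `sqrt(SE_i^2 - 1/S1)`; Kendall's tau-b (tie-corrected)
  between those deviations and the study variances is tested by exact
  permutation enumeration for k <= 8 (no ties) and otherwise by the
  tie-corrected normal approximation without continuity correction.
- **Trim-and-fill** uses the L0 estimator: at each iteration the studies
  are centred at the fixed-effects estimate of the trimmed set, and with
  T the rank-sum of absolute deviations on the over-represented side,
  `k0 = max(0, round((4T - n(n+1)) / (2n - 1)))`; the k0 most extreme
  studies on that side are trimmed and the procedure repeats until k0
  stabilizes (or 20 iterations, returning the last iterate with a
  warning). Filling mirrors the trimmed studies about the final centre;
  the adjusted estimate re-pools observed plus filled studies under the
  same model as the primary analysis. `side = "auto"` imputes on the side
  with the smaller absolute-deviation rank-sum.

The pipeline runs trim-and-fill only when Egger or Begg is significant at
alpha, mirroring the practice of attempting adjustment once bias is
suspected; an always-run mode is available by calling `trim_and_fill()`
directly.

Two properties of the L0 estimator deserve explicit documentation, since
both are verified (not worked around) by the test suite. First, it is
deliberately conservative: on a funnel built from exact mirror pairs with
its three most negative studies removed, the rank algebra forces the
rank-sum T to 22 for any positive centre, so the iteration settles at
k0 = 2, one short -- independent reference implementations behave
identically. Exact recovery of all three suppressed studies requires a
funnel whose surviving core pins the centre (a precise, near-symmetric
core with a small-study tail), and the acceptance suite uses such a
construction. Second, automatic side selection degrades on small
surviving pools; positive controls with a known suppression direction
should fix `side` explicitly.

**Power.** The Hedges-Pigott normal approximation gives the power of the
pooled Z-test at an assumed true log OR delta:
`1 - pnorm(z - lambda) + pnorm(-z - lambda)` with
`lambda = delta / SE_pooled`. The assumed delta is a required user input
(`power_delta` in the run configuration); no default effect size is
invented, and the report omits the column when none is supplied.

## Risk conversion and panel scoring

The pooled odds ratio updates a baseline (pre-test) risk through odds
space: pre-test odds `p/(1-p)`, post-test odds `OR x` pre-test odds,
post-test risk `odds/(1+odds)`. The default pre-test risk is 0.08, an
assumed 8% population prevalence of AUD; all arithmetic is kept in full
precision, and the reporting layer rounds to two decimals. The conversion
is strictly monotone in both arguments, exactly invertible, and composes
multiplicatively through odds -- all asserted as properties.

Panel scoring sums risk-allele dosages (0/1/2) across the eleven panel
alleles and dichotomizes the count: reaching 4 flags drug risk, reaching
7 flags AUD risk (both configurable). Counts at or above the cutoff
flag risk: higher counts mean more risk alleles, and with the default
ordering an AUD flag always implies a drug flag. Because published
descriptions of such panels do not always state whether alleles are
counted by dosage or by carrier status, a carrier mode (each allele
contributing at most 1, maximum 11) is provided alongside the default
dosage mode (maximum 22). The panel ships with ten genes and eleven
alleles; DRD4 contributes two (its promoter SNP and the exon-3 48 bp
VNTR 7-repeat), which is how ten genes yield eleven alleles.

## The synthetic-data generator

`generate_studies()` emulates a case-control literature for one
polymorphism: per-study true log ORs drawn from
`Normal(log(true_or), tau2)`; the control allele frequency mapped to the
case frequency through the odds relation; arm sizes uniform over a
configurable range; allele counts binomial with two draws per subject.
Defaults describe a typical candidate-gene literature and are the
conditions under which the pipeline is validated: true OR 1.5, tau2 0.05,
30 studies, control allele frequency 0.30 (risk-allele frequencies near
one third are typical of the panel's variants in unscreened controls),
arms of 500-2000 subjects. `gars_study_presets()` supplies per-gene
literature scales (study counts and case/control totals) for fixtures
that reproduce small-literature behaviour -- e.g. a single-study gene is
flagged insufficient rather than pooled, and small-sample genes fail to
reach significance, qualitatively matching the published pattern for
DRD1, GABRB3 and MAO-A.

Publication suppression operates at the study level: a study failing the
significance rule (two-sided by default; one-sided for directional
selection, the mechanism that produces the funnel asymmetry Egger, Begg
and trim-and-fill target) is discarded with the configured probability.
The pool shrinks -- suppressed studies are not regenerated -- so heavy
suppression of a null literature leaves a small, biased pool, exactly the
pathology the bias module must detect. `generate_genotypes()` adds
controllable HWE deviation via an inbreeding coefficient
(`(p^2 + fpq, 2pq(1-f), q^2 + fpq)`), and `generate_panel_subjects()`
draws independent binomial dosages per panel allele.

Every generator is a pure function of its configuration, including the
seed, and restores the caller's RNG state.

**What the generator does not emulate** -- and hence what passing tests do
not establish about real literatures: confounding by ancestry or
population stratification; genotyping error (beyond the HWE-deviation
knob); correlated effects across polymorphisms or linkage between panel
alleles (panel dosages are independent); covariate-driven heterogeneity
with structure (random effects are exchangeable normal); selective
*reporting* within studies, as opposed to suppression of whole studies;
and control groups that are themselves imperfectly screened. Results on
synthetic data validate the statistical machinery, not the biological
claims.

## Validation design and problem sizes

The test suite validates each operation against an independent route:
Fisher's exact test against direct hypergeometric enumeration over every
2x2 table with total at most 40; the exact HWE p-value against a Monte
Carlo pairing of the observed alleles; Begg's exact p against full
permutation enumeration; the pooling, regression-test and trim-and-fill
estimates against `metafor` on shared inputs; and closed forms wherever
they exist (Q and I-squared on two-study cases, DL tau2 by hand, the MH
estimator under homogeneity).

Calibration is established by simulation at sizes chosen to keep the full
suite comfortably within a few minutes on one core while leaving sampling
error well inside the asserted bands: 95% CI coverage of the DL pooled OR
over 500 replicates at (OR 1.5, tau2 0.05, k 30), accepted within 92-98%
(the DL interval with normal quantiles is known to undercover mildly at
moderate k -- a limitation, not a defect of the implementation);
median tau2-hat over 200 replicates at (tau2 0.1, k 40) within 30% of
truth; Egger type-I error over 1000 null replicates at k 20 within 3-7%;
HWE rejection rate over 1000 equilibrium replicates within the same band;
and the trim-and-fill sandwich property (adjusted estimate between the
observed pooled estimate and the truth) in at least 80% of 200 heavily
suppressed literatures (k 75 generated, arms 50-500, one-sided
suppression probability 0.9) with the suppression side supplied, as a
positive control should.

## Numerical conventions and degenerate inputs

- Normal and chi-squared quantiles come from the distribution functions,
  never hard-coded constants.
- p-values are clamped to [0, 1]; I-squared to [0, 1]; k0 to [0, k-1].
- Ties use mid-ranks throughout (Wilcoxon, Begg, trim-and-fill ranks).
- A single-study "pool" is the study itself; requesting random effects on
  it falls back to fixed effects with a logged note, since tau2 is not
  estimable.
- Genes with fewer than two usable studies are flagged
  `insufficient_data` and reported without a post-test risk, mirroring
  the dash convention of published summary tables; genes with fewer than
  three studies skip the bias diagnostics, which are undefined there.
- Report tables round to two decimals (half-up); the JSON sidecar retains
  full precision. Identical inputs and configuration produce byte-identical
  sidecars.

## Known limitations

The DL interval undercovers at small k (no Knapp-Hartung adjustment is
offered); Egger's test has low power against selection that truncates on
the z-scale, particularly in small pools diluted by randomly surviving
null studies; trim-and-fill assumes the suppression mechanism is
"the most extreme studies on one side", which study-level significance
suppression only approximates; and the risk conversion treats the pooled
OR as a likelihood ratio for a binary marker, which overstates the update
when the allele is common in controls. These are properties of the
methods themselves, retained deliberately: the package's purpose is to
implement the standard validation chain faithfully and to make its
behaviour measurable.
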