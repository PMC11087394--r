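---
title: "Methods and design of mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `mrscreen`, the exact
estimator formulas, and the design decisions — especially those of the
synthetic-data generator, whose defaults define the package's study
conditions for calibration.

## 1. The two-sample MR model

A genetic variant $j$ is a valid instrument for exposure $X$ on outcome
$Y$ if it (i) associates with $X$, (ii) shares no confounder with
$X$–$Y$, and (iii) affects $Y$ only through $X$. Under a linear
structural model with per-allele exposure effect $\gamma_j$ and causal
effect $\beta$, the variant's outcome association is
$\Gamma_j = \beta\,\gamma_j$. In the two-sample design
$\hat\gamma_j, \hat\Gamma_j$ come from non-overlapping GWAS, so their
sampling errors are independent. For a binary outcome the GWAS betas are
log-odds ratios, and $\beta$ is interpreted on the log-odds scale.

### Wald ratio

For one instrument,
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with the standard first-order
SE $\mathrm{se}_j = \mathrm{se}(\hat\Gamma_j) / |\hat\gamma_j|$
(`wald_ratio`). The exposure-side uncertainty is ignored (the NOME
approximation), the field convention for genome-wide-significant
instruments. A zero exposure beta raises a typed
`mrscreen_degenerate_instrument` error rather than returning an infinity.

### Inverse-variance-weighted estimator

With weights $w_j = \hat\gamma_j^2 / \mathrm{se}(\hat\Gamma_j)^2$
(`mr_ivw`):

$$\hat\beta_{IVW} = \frac{\sum_j \hat\gamma_j \hat\Gamma_j / \mathrm{se}(\hat\Gamma_j)^2}{\sum_j \hat\gamma_j^2/\mathrm{se}(\hat\Gamma_j)^2},
\qquad
\mathrm{se}_{fixed} = \Big(\sum_j w_j\Big)^{-1/2}.$$

This equals weighted least squares of $\hat\Gamma_j$ on $\hat\gamma_j$
through the origin. The default `multiplicative_random` mode inflates the
fixed SE by $\sqrt{\max(1,\, Q/(J-1))}$, where $Q$ is Cochran's
statistic; heterogeneity widens intervals but never narrows them. With a
single instrument the function returns exactly the Wald ratio (special
case, not a limit of the formulas).

### Heterogeneity and pleiotropy

Cochran's $Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW,fixed})^2$ is
referred to $\chi^2_{J-1}$ (`cochran_q`). MR-Egger (`mr_egger`) fits
weighted least squares of $\hat\Gamma_j$ on $\hat\gamma_j$ *with* an
intercept after orienting all $\hat\gamma_j \ge 0$; a nonzero intercept
indicates directional pleiotropy. SEs are divided by
$\min(\hat\sigma, 1)$ — the multiplicative-random floor — and tested on
$J-2$ degrees of freedom; Egger requires at least 3 instruments.
`leave_one_out` re-estimates IVW dropping each variant in turn.

## 2. Instruments and harmonization

Candidates must pass $p < 5\times10^{-8}$ (strict inequality). Greedy
clumping then walks candidates in order of increasing $p$ (ties broken by
`variant_id`), retains the current best, and removes any remaining
candidate on the same chromosome within 10,000 kb whose $r^2$ with it is
$\ge 0.001$. Variants absent from the LD matrix are assumed uncorrelated,
with a warning. The tie-break rule and the index-to-candidate window
definition make the output a deterministic function of the inputs; the
test suite checks equivalence against an independently coded brute-force
oracle on random instances.

Harmonization joins on `variant_id` and aligns the outcome record to the
exposure's effect allele, accepting four codings: identical alleles,
swapped (outcome beta negated), strand-complemented, and
complement-swapped (negated). Palindromic variants (A/T, C/G) are dropped
unconditionally — allele-frequency-based alignment is deliberately not
attempted, trading a few instruments for zero risk of silent strand
errors. Variants duplicated in either source are dropped at this stage
(upstream validation only flags them, so the drop is auditable). Every
exclusion is recorded with a reason; zero harmonizable rows raises a
typed `mrscreen_no_harmonizable` condition so that batch screens can skip
and record rather than crash.

## 3. Two-step mediation

With mediator $M$, the two-step estimates are $\hat\beta_{EM}$ (exposure
instruments vs the mediator GWAS), $\hat\beta_{MO}$ (the mediator's own
instruments vs the outcome GWAS), and the total $\hat\beta_{EO}$. Then

$$\text{indirect} = \hat\beta_{EM}\hat\beta_{MO}, \qquad
\mathrm{se}^2_{indirect} = \hat\beta_{EM}^2\,\mathrm{se}_{MO}^2 + \hat\beta_{MO}^2\,\mathrm{se}_{EM}^2,$$

the first-order delta method for a product, with no covariance term
because the legs come from non-overlapping samples. The direct effect is
$\hat\beta_{EO} - \text{indirect}$ and the proportion mediated is
$\text{indirect}/\hat\beta_{EO}$ — reported unclamped, flagged (with a
warning) when indirect and total effects disagree in sign, and `NA` when
the total effect is exactly zero. The omitted second-order term
$\mathrm{se}_{EM}^2 \mathrm{se}_{MO}^2$ makes the delta SE a slight
underestimate; the acceptance suite bounds the discrepancy against the
Monte-Carlo SD of a product of independent normals (< 2% at the package's
operating signal-to-noise).

`proportion_from_or` is a replay mode: given three published odds
ratios it computes the proportion mediated from their logarithms, for
desk verification of reported mediation results from rounded ORs.

## 4. The synthetic-data generator

`simulate_triplet` draws a ground-truth study so that calibration is
checkable without external downloads. The model:

- $m$ exposure instruments with per-allele effects $\gamma_j$ drawn
  uniformly from $\pm[0.1, 0.3]$, plus null SNPs.
- **Mediator instruments**: a separate set of variants with direct
  effects $\delta_k$ on the mediator only. These are essential: if every
  mediator-associated variant acted through the exposure, the
  mediator→outcome leg would re-estimate
  $\beta_{total}/\beta_{EM}$ and the estimated proportion mediated would
  be identically 1 regardless of the truth. Real two-step MR likewise
  instruments the mediator with its own (e.g. BMI) GWAS hits, which is
  why `mediate()` takes a `mediator_instruments` argument.
- Structural effects: the mediator GWAS beta of an exposure instrument is
  $\beta_{EM}\gamma_j$; the outcome beta is
  $(\beta_{direct} + \beta_{EM}\beta_{MO})\gamma_j$ for exposure
  instruments and $\beta_{MO}\delta_k$ for mediator instruments.
- Sampling noise: each table's SE is the per-allele approximation
  $1/\sqrt{2\,n\,f(1-f)}$ for sample size $n$ and allele frequency $f$;
  observed betas are the structural values plus independent normal noise
  at that SE. p-values are two-sided normal, floored at
  `.Machine$double.xmin` so that astronomically strong signals survive
  the validator's $p > 0$ invariant (GWAS tools report tiny p-values the
  same way).
- LD: instruments head blocks of configurable size; tag variants carry
  effect $\sqrt{r^2}$ times their head's and $r^2$ as specified, so
  clumping has real work to do. Noise is drawn independently for LD
  partners — effect attenuation is modeled, error correlation is not —
  which is adequate for exercising the clumping logic but not for
  emulating realistic locus-level test-statistic correlation.
- Contamination: a configurable fraction of variants is made palindromic
  (consistently across all three tables) and a fraction is duplicated in
  the outcome table, so harmonization's drop rules are exercised on every
  simulated run.
- Determinism: all draws derive from a single integer seed via the
  splitter $s_k = (16807\,s + k) \bmod (2^{31}-1)$; identical configs
  produce byte-identical files.

Defaults were fixed once as study conditions: exposure GWAS $n=10{,}000$
(pQTL scale), mediator and outcome GWAS $n=300{,}000$ (biobank scale), 50
instruments, blocks of 5 at $r^2=0.8$, 5% palindromic, 2% duplicated, and
structural effects $\beta_{EM}=-0.02$, $\beta_{MO}=1.5$,
$\beta_{direct}=-0.09$, implying a total effect of $-0.12$ and a true
proportion mediated of $0.25$.

## 5. Calibration choices

The type-I-error acceptance check uses the **fixed-effect** IVW mode.
The generator's null is homogeneous (no pleiotropy, no effect
heterogeneity), which is exactly the regime where the fixed-effect test
is the calibrated one; the multiplicative-random mode's inflation factor
is floored at 1, so it can only widen intervals and its rejection rate
under a homogeneous null is conservative by construction. This choice was
made on that analytic ground, not by comparing observed rates. The
default for data analysis remains `multiplicative_random`, because real
instruments are rarely homogeneous and conservatism is the right failure
mode there.

Other numerical decisions:

- $z_{0.975}$ is the fixed constant `1.959964` everywhere, so confidence
  intervals are bit-reproducible across platforms.
- Summary-statistics files are written with `%.17g`, making
  write→read→write round-trips exact; pipeline outputs use the same
  format so manifests can carry stable md5 checksums.
- Normal p-values are computed as `2 * pnorm(-|z|)` and floored at
  `.Machine$double.xmin`, keeping them inside $(0, 1]$.
- Manifests record the package version, seed, config, row counts and
  checksums, but deliberately no timestamp, so a rerun of the same config
  is byte-identical.

## 6. Multiplicity in the PheWAS scan

`phewas_scan` Bonferroni-corrects by the number of phenotypes *actually
tested* (rows that failed harmonization are reported with a reason, not
silently dropped, and do not count toward the divisor) and computes
Benjamini–Hochberg q-values with `stats::p.adjust`. Each row is labeled
with the strongest significance tier it reaches
(`none`/`nominal`/`bh`/`bonferroni`).

## 7. Limitations

- SNPs only; indels are rejected at validation.
- Palindromic variants are always dropped; there is no
  allele-frequency-based rescue.
- The NOME approximation ignores exposure-side uncertainty in the Wald
  denominator; weak instruments (which the $5\times10^{-8}$ threshold
  largely excludes) would bias estimates toward the null.
- The delta-method mediation SE omits the covariance and second-order
  terms; it is appropriate for non-overlapping samples and moderate
  relative SEs.
- The simulator's independent-noise-within-LD-block design understates
  locus-level correlation of test statistics; conclusions about clumping
  correctness transfer, conclusions about locus-wise error rates would
  not.
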