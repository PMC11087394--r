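# mrscreen

Two-sample Mendelian randomization (MR) for screening molecular exposures
— such as plasma protein levels — against a disease outcome, with
two-step mediation analysis through an intermediate risk factor,
phenome-wide (PheWAS-style) specificity scanning, and a fully synthetic
GWAS summary-statistics generator for calibration and testing.

## The science

Mendelian randomization uses genetic variants as instrumental variables:
because alleles are assigned at conception, a variant that robustly
alters an exposure (e.g. a cis-pQTL for a circulating protein) provides a
randomization device for estimating the causal effect of that exposure on
an outcome, free of classical confounding and reverse causation. In the
*two-sample* design the variant–exposure and variant–outcome associations
come from non-overlapping GWAS, so the whole analysis runs on public
summary statistics.

`mrscreen` implements the full screening workflow:

1. **Summary-statistics IO** (`read_sumstats`, `sumstats`): validated
   tables with per-row invariants (alleles in A/C/G/T, `se > 0`,
   `p ∈ (0, 1]`, 1-based positions) and exact write/read round-trips.
2. **Instrument selection** (`select_instruments`): genome-wide
   significance (`p < 5e-8`, strict) followed by greedy LD clumping
   (`r² < 0.001` within a 10,000 kb window, best p first, ties broken by
   variant id).
3. **Harmonization** (`harmonize`): aligns outcome effects to the
   exposure's effect allele, resolving swapped and strand-complemented
   allele codings, dropping palindromic (A/T, C/G) variants and
   duplicated ids, and auditing every drop with a reason.
4. **Estimation** (`mr_ivw`, `wald_ratio`): inverse-variance-weighted
   meta-analysis of per-variant Wald ratios, with fixed-effect and
   multiplicative-random-effect standard errors (the default inflates the
   fixed SE by `sqrt(max(1, Q/(J−1)))`); a single instrument reduces
   exactly to its Wald ratio.
5. **Sensitivity** (`mr_sensitivity`): Cochran's Q heterogeneity test,
   MR-Egger intercept (directional pleiotropy), and leave-one-out
   estimates.
6. **Mediation** (`mediate`, `indirect_effect`): two-step MR — the
   exposure→mediator and mediator→outcome effects are multiplied to give
   the indirect effect, with a delta-method SE
   (`√(β_EM² se_MO² + β_MO² se_EM²)`; no covariance term under the
   two-sample design); the proportion mediated is `indirect / total`.
7. **PheWAS scan** (`phewas_scan`): the same instruments against a
   battery of phenotypes, with Bonferroni and Benjamini–Hochberg
   multiplicity control, to check whether an exposure's effect is
   outcome-specific.
8. **Synthetic data** (`sim_config`, `simulate_triplet`,
   `simulate_phenotype_battery`): a generative model with known ground
   truth — per-allele effects, LD blocks with tag variants, palindromic
   and duplicated contamination, and a structural
   exposure→mediator→outcome path — used by the test suite to verify
   calibration end to end.
9. **Pipeline + CLI** (`run_screen`, `run_mediation`, `run_phewas`,
   `run_simulate`, `inst/cli/mrscreen.R`): config-driven batch runs that
   write tab-delimited results plus a manifest with md5 checksums.

## Worked example

Everything below is real output, reproducible with the seed shown.

```r
library(mrscreen)

# 1. Simulate a study: exposure pQTL GWAS + mediator and outcome GWAS
#    sharing a known structural model (defaults imply a true total effect
#    of -0.12 on the log-odds scale and 25% mediation).
cfg <- sim_config(seed = 20240301)
sim <- simulate_triplet(cfg)
sim$exposure
#> <sumstats> exposure (quantitative, sample sim_exposure): 300 variants (0 dropped at validation)

# 2. Instruments: genome-wide significant, then LD-clumped
instr <- select_instruments(sim$exposure, sim$ld)
instr
#> <instrument_set> exposure: 50 instruments (239 candidates, 189 removed by clumping)

# 3. Harmonize against the outcome GWAS and estimate
h <- harmonize(instr, sim$outcome)
h
#> <harmonized_table> exposure vs outcome: 46 variants retained, 4 dropped
mr_ivw(h)
#> <mr_estimate> ivw_mre (46 SNPs): beta -0.1148 (SE 0.002046), OR 0.8916 [0.8880, 0.8952], p 2.23e-308

# 4. Sensitivity analyses
sens <- mr_sensitivity(h)
#    Q = 48.6 on 45 df (p = 0.331); Egger intercept = -0.0002 (p = 0.89)

# 5. Two-step mediation through the simulated risk factor
med_instr <- select_instruments(sim$mediator, sim$ld, exposure_id = "mediator")
med <- mediate(instr, sim$mediator, sim$outcome, med_instr)
med$result
#> <mediation_result> indirect -0.02646 (SE 0.003108, p 1.69e-17), direct -0.08832, proportion mediated 23.05%
sim$truth$proportion_mediated
#> [1] 0.25
```

The mediation module also has a replay mode for desk-checking published
results from their printed odds ratios. For a protein with
OR 0.9669 on body-mass index, OR 1.0030 of body-mass index on childhood
asthma, and total OR 0.9980 on asthma:

```r
proportion_from_or(or_em = 0.9669, or_mo = 1.0030, or_eo = 0.9980)$proportion_mediated_pct
#> [1] 5.036429
```

A PheWAS scan over a simulated phenotype battery (3 of 12 phenotypes
truly associated):

```r
battery <- simulate_phenotype_battery(sim_config(seed = 20240301),
                                      n_phenotypes = 12,
                                      frac_truly_associated = 0.25)
instr <- select_instruments(battery$exposure, battery$ld)
scan <- phewas_scan(instr, battery$phenotypes)
head(scan[, c("phenotype_id", "n_snps", "beta", "se", "pval", "p_bh", "significant_at")], 5)
#>     phenotype_id n_snps    beta      se      pval      p_bh significant_at
#> 1 phenotype_0006     48 0.05126 0.00197 3.50e-149 4.20e-148     bonferroni
#> 2 phenotype_0002     48 0.04954 0.00191 8.37e-148 5.02e-147     bonferroni
#> 3 phenotype_0012     48 0.04904 0.00208 2.56e-123 1.02e-122     bonferroni
#> 4 phenotype_0011     48 0.00292 0.00191  1.27e-01  3.80e-01           none
#> 5 phenotype_0001     48 0.00116 0.00191  5.46e-01  9.39e-01           none
```

The three Bonferroni-significant phenotypes are exactly the truly
associated ones (`battery$truth$associated_ids`).

## Command-line interface

`inst/cli/mrscreen.R` wraps the pipeline functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mrscreen.R", package = "mrscreen"))')" \
  simulate --config study.yaml --out-dir data/ --seed 7
# likewise: screen / mediate / phewas, with --p-threshold, --clump-r2,
# --clump-kb, --alpha overriding the config file
```

## Limitations

- SNPs only (indels rejected); palindromic variants are always dropped
  rather than frequency-aligned.
- The delta-method SE for the indirect effect omits the covariance term,
  which is appropriate only when the two legs come from non-overlapping
  samples.
- The simulator draws independent noise for LD partners (effect sizes are
  attenuated by `√r²` but sampling errors are uncorrelated); it is
  designed for calibration of the screening pipeline, not for emulating
  realistic correlated test statistics within a locus.
- See `vignettes/mrscreen-methods.Rmd` for the statistical model, all
  estimator formulas, and the design decisions behind the generator.
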