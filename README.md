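# sipiScan

Pattern-based SNP-SNP interaction scanning for case-control association
studies, with single-variant analysis, Bonferroni multiplicity
thresholds, bootstrap internal validation, and a synthetic cohort
generator.

## What problem this solves, and for whom

Candidate-gene studies of binary clinical outcomes — the motivating
application is prostate-cancer aggressiveness (high vs. low) in
European-American and African-American patient strata genotyped for 11
folate/one-carbon-metabolism polymorphisms — often find no significant
individual variants, while pairwise interactions carry medium-to-large
effects. The conventional interaction test (additive coding for both
variants, full hierarchical model) probes only one of many biologically
plausible joint-effect shapes and is prone to false negatives.

`sipiScan` is for statistical geneticists and epidemiologists running
such candidate-panel analyses. For every variant pair it searches a
catalogue of **45 interaction patterns** crossing

- inheritance-mode combinations **AA, DD, DR, RD, RR**
  (A = additive, D = dominant, R = recessive; first letter = first SNP),
- model structures **Full** (x1 + x2 + x1·x2), **M1_int** (x1 + x1·x2),
  **M2_int** (x2 + x1·x2) and **int** (interaction only),
- risk directions **o**riginal (minor-allele coding) and **r**everse
  (major-allele coding),

giving 5 × (1 + 2 + 2 + 4) = 45 logistic models per pair (e.g.
`DD_Full`, `DD_M1_int_r1`, `DR_int_or`), every one adjusted for age,
study site and genetic-ancestry proportion. The pattern with the lowest
BIC = −2·logL + k·log(n) is selected and its product-term odds ratio,
95% CI and Wald p reported. Single variants are tested under the best
of the three inheritance modes; family-wise thresholds are α/m
(0.05/11 = 0.0045 for variants, 0.05/55 = 0.0009 for pairs). Pairs with
p < 0.05 are then put through **bootstrap internal validation**: 500
resamples of individuals, refit of the fixed selected pattern, and the
**3pRule** per replicate (p_pair < 0.01, p_pair < p_SNP1,
p_pair < p_SNP2); a pair is selected when p < 0.05 and more than 65% of
replicates are significant.

Because the motivating cohort is access-controlled, the package ships a
generator (`simulateStudyCohort()`) that reproduces the strata's
statistical structure — Hardy-Weinberg genotypes at the published MAFs,
the strong EA LD pair (r² = 0.86), race-reversed minor alleles,
covariate distributions, marginal prevalences 21.4% / 30.6% — with
configurable interaction effects, so the full pipeline runs end to end
with no restricted data.

## Worked example

Simulate an EA-profile cohort of 3,000 patients with one planted
protective interaction — pattern `DR_int_or` (dominant rs1801133 ×
reverse-recessive rs2236225), generating OR = 0.59 — then scan all 55
pairs and validate:

```r
library(sipiScan)

co <- determineMinorAlleles(simulateStudyCohort("EA", n = 3000,
        effect = effectSpec("DR_int_or", log(0.59)),
        effect_pair = c("rs1801133", "rs2236225"), seed = 11))
co
#> SnpCohort (stratum EA): 11 variants x 3000 samples
#>   high-aggressive: 636/3000 (21.2%)
#>   missing genotype calls: 0

pairTab <- scanAllPairs(co)
renderPairTable(head(pairTab, 3))
#>              SNP Pair Gene1  Gene2   Pattern       OR (95% CI) p-Value
#> 1 rs1801133_rs2236225 MTHFR MTHFD1 DR_int_or 0.62 (0.52, 0.74)   0.000
#> 2 rs2274976_rs1801133 MTHFR  MTHFR DD_int_ro 0.66 (0.55, 0.79)   0.000
#> 3  rs1801133_rs622506 MTHFR  MTHFS DR_int_rr 1.47 (1.23, 1.76)   0.000
```

The planted pair tops the table: the scan selects the generating
pattern `DR_int_or` and estimates OR = 0.62 (truth 0.59) — patients
carrying the rs1801133 minor allele (GA/AA) who are *not* rs2236225
minor-homozygotes (CC/CT) have roughly 0.6 times the odds of
high-aggressive disease of everyone else. Bootstrap validation then
separates the real signal from the greedy scan's runners-up, and the
prevalence grid shows the partition on the genotype scale:

```r
val <- validatePairs(co, pairTab, B = 500, seed = 101)
renderPairTable(selectSignificantPairs(pairTab, val))
#>              SNP Pair Gene1  Gene2   Pattern       OR (95% CI) p-Value Significance%
#> 1 rs1801133_rs2236225 MTHFR MTHFD1 DR_int_or 0.62 (0.52, 0.74)   0.000          90.4
#> 2 rs2274976_rs1801133 MTHFR  MTHFR DD_int_ro 0.66 (0.55, 0.79)   0.000          70.0

prevalenceGrid(co, "rs1801133", "rs2236225", pattern = "DR_int_or")
#> Prevalence grid, overall 0.21 (n=3000); * = pattern cells
#>    CC           CT           TT
#> GG 0.23 (428)   0.27 (643)   0.24 (251)
#> GA 0.14 (430) * 0.18 (670) * 0.27 (255)
#> AA 0.21 (106) * 0.18 (158) * 0.14 (59)
```

The planted pair passes validation at 90.4% significance; one
correlated runner-up survives at 70.0% — a reminder that bootstrap
stability filters, but does not abolish, the greedy scan's selection
noise. Each grid cell prints the outcome prevalence and cell size; `*`
marks the cells the selected pattern groups as the exposure class
(prevalence ~0.14-0.18 inside vs. ~0.23-0.27 in the reference rows).

A shell driver for the whole pipeline (simulate or read data →
single-variant scan → pair scan → bootstrap → selection, with TSV
outputs and a JSON manifest) is at `inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --stratum EA --seed 7 --B 500 --out results/ea
```

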