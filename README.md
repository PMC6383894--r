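# hwexeq

Equivalence ("goodness-of-fit") testing for Hardy-Weinberg equilibrium
at X-chromosomal diallelic markers.

## The problem

Marker quality control filters SNPs that deviate from Hardy-Weinberg
equilibrium (HWE). The standard Pearson χ² procedure tests *lack* of fit:
a non-significant p-value never demonstrates compatibility with the
model, and the popular shortcut of keeping a marker because p > 0.05
controls no error rate (it can "declare HWE" under real disequilibrium
up to ~95% of the time in small samples, and its power does not grow with
n). On the X chromosome the problem is compounded: males are hemizygous,
so their data are allele counts, and HWE additionally requires equal
allele frequencies in the two sexes.

`hwexeq` implements the equivalence-testing solution for X-linked
markers, for analysts doing GWAS quality control and for statisticians
planning studies that must certify marker compatibility.

## The method

For female genotype frequencies (π₁, π₂, π₃) (AA/AB/BB) and male
A-allele frequency p_Y, disequilibrium is measured by two signed log
components,

- Δf± = log π₂ − (log π₁ + log π₃)/2 − log 2 (log relative excess
  heterozygosity; 0 under HWE),
- Δm± = logit(p_X) − logit(p_Y) with p_X = π₁ + π₂/2 (log odds ratio
  between the sexes' allele frequencies),

combined as Δ = √(Δf² + Δm²). The hypotheses are H₀: Δ ≥ ε versus
H₁: Δ < ε with default margin ε = √2·log 1.4 ≈ 0.4758. The test computes
the plug-in estimate Δ̂ from counts (x₁, x₂, x₃; y of n₂) and rejects
H₀ — establishing approximate compatibility — when

Δ̂ + z₁₋α · τ̂ / √(n₁+n₂) < ε,

where τ̂² is the delta-method variance of √N·Δ̂. The package also
provides the exact finite-sample rejection probability by full
enumeration of the trinomial × binomial outcome space, the extended
χ distribution (the non-Gaussian limit of √N·Δ̂ under perfect
equilibrium), closed sample-size formulas for null and non-null
alternatives, and a Monte Carlo harness contrasting the test with the
inverted χ² rule.

## Worked example

Counts for SNP rs6646338 (GENEVA venous-thrombosis GWAS): 651 females
genotyped 230/314/107 for AA/AB/BB, and 399 of 604 males carrying A.

```r
library(hwexeq)
hwx_test(hwx_counts(230, 314, 107, n2 = 604, y = 399, snp_id = "rs6646338"))
#> Equivalence test for HWE at an X-chromosomal SNP
#>   SNP:            rs6646338
#>   delta_hat:      0.2835  (delta_f = 0.0008, delta_m = -0.2835)
#>   tau_hat_sq:     13.2641
#>   upper 95% bound: 0.4526   margin: 0.4758
#>   decision:       + (approximate HWE compatibility established)
```

The point estimate Δ̂ = 0.2835 is driven almost entirely by the
between-sex allele-frequency difference (Δm = −0.2835; the female
genotypes are almost perfectly in HWE, Δf = 0.0008). Its 95% upper
confidence bound, 0.4526, falls below the margin 0.4758, so the marker
passes: any true disequilibrium is, with 95% confidence, below the
irrelevance threshold.

Planning a study that should establish compatibility of a SNP with
allele frequency 0.5 in both sexes (perfect-HWE best case) with 80%
power:

```r
sample_size_null(pop_config(0.25, 0.5, pY = 0.5, lam = 1/2), power = 0.8)
#> Sample size for the HWE equivalence test (null alternative)
#>   formula N:  556.20
#>   n1 (females): 279   n2 (males): 279
#>   approximate power at (n1, n2): 0.8020 (target 0.80)
#>   alpha = 0.050, epsilon = 0.4758, boundary-variance rule: max_sigma_tilde

exact_rejection_prob(0.25, 0.5, pY = 0.5, n1 = 279, n2 = 279)[1]
#> [1] 0.82359
```

The exact enumeration confirms the formula's design attains (slightly
exceeds) the target power.

## Command line

A wrapper script is installed at `inst/cli/hwexeq`
(`Rscript inst/cli/hwexeq <subcommand> ...`); subcommands `test`,
`exact-power`, `power-approx`, `samplesize`, `simulate`, and `qchi` map
onto the functions above. Counts are read from a minimal TSV/CSV with
columns `snp_id, x1, x2, x3, n2, y` (see
`inst/extdata/geneva_table5.tsv`). To produce that table from standard
genotype files: restrict to non-pseudoautosomal X SNPs, count female
genotypes per marker (e.g. `bcftools query` or PLINK `--geno-counts` on
the female subset), and count male carriers of the A-coded allele among
males; column order defines which allele is "A".

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch — exact levels at boundary configurations, exact power against
null alternatives, the worked per-SNP examples, a variance ratio, and
designed sample sizes with their exact-power cross-check — and writes
them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
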