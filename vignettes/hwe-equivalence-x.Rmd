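---
title: "Establishing Hardy-Weinberg compatibility of X-chromosomal markers"
author: "hwexeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Establishing Hardy-Weinberg compatibility of X-chromosomal markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwexeq)
```

## Why an equivalence test

Marker quality control in genetic association studies routinely filters
SNPs whose genotype distribution departs from Hardy-Weinberg equilibrium
(HWE). The classical Pearson χ² procedure, however, tests *lack* of fit:
agreement with HWE is its null hypothesis, so a non-significant p-value
never demonstrates compatibility. Inverting the χ² test — keeping a
marker because p > 0.05 — controls no error rate at all: in small samples
the "declare HWE" rate under real disequilibrium can approach 95%, and in
very large samples the same rule becomes absurdly conservative while its
power against perfectly equilibrated markers does not increase with n
(the `monte_carlo_compare()` harness makes both failures visible).

Establishing compatibility requires an *equivalence* test, in which
approximate agreement with the model is the alternative hypothesis:

H0: Δ ≥ ε  versus  H1: Δ < ε,

where Δ measures the distance between the true genotype distribution and
the nearest HWE-conforming one and ε is the largest distance considered
irrelevant. Rejecting H0 then establishes, with controlled type-I error,
that any deviation from the model is below the margin.

## The distance measure on the X chromosome

X-chromosomal markers add two complications: males are hemizygous, so
their data are allele counts rather than genotype triples, and HWE
additionally requires equal allele frequencies in the two sexes. The
package therefore measures disequilibrium by two signed components:

* **Females** — the log relative excess heterozygosity (REH). With
  genotype frequencies (π1, π2, π3) for AA/AB/BB, REH = π2/(2√(π1π3)),
  which is 1 under HWE, and
  Δf± = log π2 − (log π1 + log π3)/2 − log 2.
* **Males** — the log odds ratio between the female allele frequency
  pX = π1 + π2/2 and the male allele frequency pY:
  Δm± = logit(pX) − logit(pY).

The combined distance is the Euclidean norm Δ = √(Δf² + Δm²), so the
region of acceptable configurations is a disc of radius ε in the
(Δf±, Δm±) plane.

**Margin.** Conventional per-component margins are log 1.4 ≈ 0.336 for
|log REH| and log 1.5 ≈ 0.41 for the log odds ratio; the tighter one is
adopted for both. The default combined margin is the radius of the
smallest circle containing the square with half-edge log 1.4, i.e.
ε = √2·log 1.4 ≈ 0.4758 (`hwx_margin()`). Note that √2·log 1.4, not
2·log 1.4 = 0.673, is the value consistent with the circle-through-corner
construction; the package does not hard-code the loosely rounded 0.48.

## The test

The plug-in estimator Δ̂ replaces all population frequencies by observed
proportions. √N(Δ̂ − Δ) is asymptotically normal (N = n1 + n2) with
variance τ² = (Δf²σf² + Δm²σm²)/Δ², a weighted mean of the component
variances

* σf² = (1/λ)·((1/4)(1 − π2)/(π1π3) + 1/π2),
* σm² = 1/((1−λ) pY (1−pY)) + (π1 + π2/4 − pX²)/(λ pX²(1−pX)²),

with λ = n1/N the female fraction. (The second expression is the
delta-method variance of the empirical logit difference; π1 + π2/4 − pX²
is n1 times the sampling variance of the empirical female allele
frequency.) The test rejects H0 — establishing compatibility — when the
one-sided upper confidence bound falls below the margin:

Δ̂ + z(1−α)·τ̂/√N < ε,

with τ̂ the plug-in estimate using λ̂ = n1/N. No continuity corrections
are applied anywhere.

```{r}
cts <- hwx_counts(230, 314, 107, n2 = 604, y = 399, snp_id = "rs6646338")
hwx_test(cts)
```

**Degenerate counts.** Any zero among {x1, x2, x3, y, n2 − y} leaves Δ̂
undefined. The default policy is to refuse such input
(`hwx_degenerate_error`); `sparse = "correct"` opts into the usual sparse
contingency-table repair — every zero cell becomes 1, compensated from
the largest cell of the same sex stratum so n1 and n2 are preserved
(e.g. female counts (651, 0, 0) → (649, 1, 1)). The correction alters
data, so it is never applied silently.

**Zero-distance convention.** The weights in τ² are undefined at Δ̂ = 0,
an outcome with positive probability in finite samples. The package uses
the symmetric limit (equal weights). Any convention between σf² and σm²
yields the same decision at all tabulated settings, because the resulting
bound lies far below ε whenever Δ̂ = 0 at realistic sizes.

## Exact operating characteristics

Because the outcome space of (X1, X2, X3, Y) is finite, the rejection
probability under any truth (π, pY) is an exact finite sum of
trinomial × binomial masses over the critical region.
`exact_rejection_prob()` enumerates it with log-gamma masses (safe into
the thousands), an outer vectorization over female cells and an inner
sweep over the male count. Degenerate outcomes contribute no rejection —
the estimator is undefined there and a conservative test cannot reject;
this convention is pinned down by the rare-allele boundary configuration
(π1 = 0.00564 at n = 400), whose published level 0.00726 the engine
reproduces exactly. The alternative of repairing zero-cell outcomes
inside the sum is available as `degenerate = "correct"`.

Optional pruning (`prune > 0`) skips female cells and male counts of
negligible mass; the skipped mass is summed exactly, reported, and bounds
the absolute error of the result. The default is full enumeration.

```{r}
exact_rejection_prob(0.25, 0.5, pY = 0.5, n1 = 100, n2 = 100)[1]
```

The test is conservative in finite samples: at boundary configurations
(Δ = ε) the exact level stays below the nominal 5% everywhere we have
checked, converging to it slowly from below as n grows.

## Power and sample size

For *non-null* alternatives (0 < Δ* < ε) the Gaussian limit gives

POW ≈ Φ[(τ̃·zα − √N(Δ* − ε))/τ],  N = (τ̃·z(1−α) + τ·z(1−β))²/(Δ* − ε)²,

where τ is evaluated at the alternative and τ̃ at a *conjugate boundary
point*: same π1, both components moved to ε/√2 (positive sign), so the
point sits on the equivalence circle. Two genuinely open choices were
resolved empirically:

* The conjugate components are ε/√2, not ε/2 — only the former places
  the point on the circle of radius ε, and only it reproduces the
  reference designs.
* τ̃ is taken as σ̃f (the female component standard deviation at the
  conjugate point), not the Eq-15 weighted mean. The weighted-mean
  reading of "the same formulas" fails to reproduce any of the published
  sample sizes, whereas τ̃ = σ̃f reproduces all of them; both conventions
  are implemented (`convention = "sigma_f"` / `"eq_mean"`) and recorded
  in the result.

Rounding follows n1 = ⌈λN⌉, n2 = round(n1(1−λ)/λ).

For *null* alternatives (perfect equilibrium, the relevant best case) the
limit of √N·Δ̂ is not Gaussian but an extended χ law: the distribution of
√(Z1² + c²Z2²) for independent standard normals, with c = σm/σf.
`pextchi()` evaluates its CDF by the integral representation
2∫Φ(√(q²−z²)/c)φ(z)dz − (2Φ(q) − 1) using composite 96-point
Gauss-Legendre quadrature on 10 subintervals. The substitution
z = q·sin θ removes the square-root endpoint singularity of the raw
integrand; without it the same quadrature effort stalls near 7e-9
absolute error, with it the closed form at c = 1 (1 − exp(−q²/2)) is
matched below 1e-12. `qextchi()` inverts by bracketed root-finding.

Power and size against null alternatives use the refined boundary scale
max{σ̃f, σ̃m} (which improves clearly on the weighted mean):

N = (z(1−α)·max{σ̃f, σ̃m} + σf·Qc⁻¹(1 − β))²/ε².

```{r}
sample_size_null(pop_config(0.25, 0.5, pY = 0.5, lam = 1/2), power = 0.8)
```

Accuracy of the closed formulas, as re-verified by the exact engine in
the test suite: for null alternatives the attained exact power is within
about 3 points of target except in low-power (60%) settings; the
non-null formula is acceptable when n2 ≥ n1 but markedly underestimates
the requirement when females dominate (λ > 1/2) — it is a planning
heuristic, and the exact engine is the arbiter.

## Synthetic data and the comparator

`sample_counts()` and `monte_carlo_compare()` draw replicate tables from
exactly the sampling model under which all operating characteristics are
derived: multinomial(n1; π) females, binomial(n2; pY) males, independent.
The generator therefore emulates sampling noise only — not genotyping
error, missingness, population structure, or linkage between markers — so
a green Monte Carlo test establishes correctness of the procedure under
its own model, not robustness to artefacts real data may carry. Default
scenario parameters in the tests are the tabulated ones (boundary and
null configurations at n = 100–1200, 10^5 replicates); the harness is
checked against the exact engine within 4 binomial standard errors.
Reproducibility uses one `set.seed()` per harness call (single-threaded
base R generators) rather than per-replicate streams.

The lack-of-fit comparator is the 2-df combined Pearson statistic:
within-female HWE χ² (expected counts from the female allele frequency)
plus the 2×2 allele-table χ² comparing the sexes. Published comparator
rates depend on unstated variant details (corrections, exact vs
asymptotic), so the package asserts only its qualitative behavior.

## Numerical and degenerate-input choices

* Root solving for π2 uses derivative-free bracketing on
  (1e-12, 1 − π1 − 1e-12) with absolute tolerance 1e-12; the component is
  strictly monotone in π2, so the root is unique.
* Allele A is whatever the input codes as A; no minor-allele
  re-orientation is performed. Relabeling (x1↔x3, y↔n2−y) leaves the
  female component and the bound unchanged and flips the sign of the male
  component, so decisions are orientation-invariant.
* Probability masses in the exact engine are computed via `lgamma`;
  naive factorials overflow near n = 170.
* Domain violations (frequencies outside (0,1)) raise
  `hwx_domain_error`; zero-cell count tables raise
  `hwx_degenerate_error`. The two are distinct condition classes so
  callers can machine-handle sparse markers.

## Known limitations

* The test is asymptotic and conservative: at n around 100 per sex its
  exact level can be an order of magnitude below nominal, with the
  corresponding loss of power; exact enumeration should accompany any
  small-sample application.
* Only diallelic markers and the Euclidean combination are supported; a
  rectangular (Chebyshev) acceptance region via intersection-union
  testing is out of scope.
* No multiple-testing adjustment across SNPs is applied; callers own
  that choice.
* Two entries of the reference material could not be reproduced and are
  inconsistent with their own companion values: one printed variance for
  the sparse worked-example SNP (the printed bound implies a value ten
  times larger, which the package obtains), and the final digit of one
  printed rejection probability (the enumeration, verified exactly
  against brute force, gives a value one final-digit ulp away). The test
  suite documents both in place.
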