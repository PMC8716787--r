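---
title: "Testing gene–gene interaction with constrained boosted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene–gene interaction with constrained boosted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`ggiboost` tests whether two genes interact statistically in a case–control
study. A gene is a set of SNPs; sample *i* carries minor-allele counts
`G1 = (g_{1,i,1}, …, g_{1,i,p})` for gene 1 and `G2` (length *q*) for gene 2,
plus a binary phenotype. "No interaction" is formalised as additivity of the
log odds across the two SNP sets:

$$H_0:\; P(y=1 \mid G_1,G_2)
  = \frac{e^{F_1(G_1)+F_2(G_2)}}{1+e^{F_1(G_1)+F_2(G_2)}}$$

for *some* functions $F_1, F_2$. Nothing is assumed about the form of each
gene's own effect: dominance, within-gene epistasis and arbitrary LD are all
allowed under $H_0$. Only cross-gene structure is constrained, which is what
makes the test *gene-based* rather than marker-based.

The test statistic exploits a structural property of boosted regression
trees: if every tree's root-to-leaf paths split only on features from a
single declared group, the ensemble's log-odds prediction is exactly a sum
$F_1(G_1) + F_2(G_2)$. `build_constraints()` hands the two-gene partition to
the boosting engine as a feature-interaction constraint;
`audit_constraint_compliance()` re-derives the property from the fitted tree
dump rather than trusting the engine (every constrained fit in the test
suite is audited).

Two classifiers are fitted with binary logistic loss — unconstrained and
constrained — and scored by stratified k-fold cross-validated
misclassification error (probability threshold 0.5), *on the same folds*.
The statistic is the relative degradation caused by the constraint,

$$\Delta err_0 = \frac{err_{cons} - err_{orig}}{err_{orig}},$$

and its null distribution is estimated by label permutation: the whole
procedure (both models, freshly stratified folds) is rerun on each of *m*
shuffles of `y`, giving $p = \#\{i : \Delta err_i \ge \Delta err_0\}/m$.
Because the labels are exchangeable under $H_0$ and the permuted replicas
undergo the identical pipeline, the test is exact (up to the 1/m p-value
granularity) at *any* ensemble size — fidelity affects power, never level.
Ties count toward the numerator, and $p=0$ is attainable; an optional
`(count+1)/(m+1)` estimator is available when downstream adjustment cannot
tolerate zeros.

### Degenerate denominators and other numerical choices

* `err_orig = 0` makes the ratio undefined; the statistic is defined as
  `Inf` when `err_cons > 0` and `0` otherwise, preserving the ordering
  semantics of the permutation count (`Inf >= Inf` ties are counted).
* Folds are stratified by label so case/control ratios match across folds
  and no training fold can be single-class; fold assignment, permutations
  and all simulation draws derive from one master seed via a deterministic
  string-keyed hash (`derive_seed()`), so results are bit-reproducible and
  independent of worker count (permutations may fan out over a socket
  cluster).
* CV errors are averaged over folds by default; pooling the held-out
  predictions into one error is available (`aggregate = "pooled"`). With
  balanced fold sizes the two coincide.
* No early stopping: exactly `num_rounds` trees, so constrained and
  unconstrained runs face symmetric model capacity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `num_rounds` | 1000 | boosting rounds (trees) |
| `max_depth` | 3 | tree depth; 2–4 is plenty for SNP data, deeper overfits |
| `learning_rate` | 0.01 | shrinkage per round |
| `n_folds` | 10 | CV folds, stratified |
| `m` | 1000 | label permutations |
| `alpha` | 0.01 (screen), 0.05 (simulation harness) | significance level |

The defaults are the full-fidelity analysis profile. A `"desk"` profile
(`boost_config(profile = "desk")`: 100 rounds at rate 0.1) keeps the product
`learning_rate × num_rounds = 10` while cutting compute tenfold; the same
invariance guides the still smaller configurations used in the package's
own checks. Since only *relative* performance of two equally sized
ensembles enters the statistic, the test remains valid at every profile;
low-frequency signals, however, need the fine-grained profile to surface
(see Limitations).

## The synthetic data generator

The simulator emulates a small two-gene study: a pool of `H = 90` phased
haplotypes over 6 + 7 SNPs, one gene with strong internal LD (block r² 0.7)
and one with weak LD (0.2), MAFs spread over 0.2–0.4, genes mutually
unlinked. Haplotypes are drawn from a latent Gaussian AR(1) chain per gene;
alleles are assigned by *empirical-quantile* thresholding, so realized MAFs
match their targets to within 1/H, and the latent correlation is calibrated
numerically (orthant probability by quadrature) so the binary allele r²
matches the requested block value. `r² = 1` duplicates columns and is
refused for unequal MAFs, `r² = 0` gives independence.

Individuals are sums of two haplotypes drawn uniformly with replacement, so
genotypes follow Hardy–Weinberg products of pool frequencies and inherit the
pool's LD. Disease status comes from a two-locus penetrance model on one
causal SNP per gene: odds $\gamma(1+\theta)^{k(g_1,g_2)}$ with the exponent
mask *k* selecting the model. Six classical masks are built in (jointly
recessive–dominant, dominant–dominant, XOR, threshold, multiplicative,
recessive–recessive); a mask is data, and a user-supplied 3×3 exponent table
is accepted. Since the "jointly dominant–dominant" and "threshold" patterns
coincide in some taxonomies, this package distinguishes them as: effect once
*both loci* carry ≥ 1 minor allele (DD) versus effect once the *total*
minor-allele count across the loci reaches 2 (threshold, which also fires
for a single homozygous locus). The baseline odds γ are solved by bisection
on `[prevalence·1e-6, 1]` so that `Σ penetrance(g)·Pr(g) = prevalence` to
1e-10 (prevalence is monotone in γ); at θ = 0 the closed form
`γ = p/(1-p)` is used directly. Genotype probabilities for the constraint
are products of the two genes' HWE marginals at the pool's empirical allele
frequencies — the genes are unlinked by construction, so the product form is
the generator's own truth. Cases and controls are filled by rejection
sampling with an attempt cap (default 1e7 draws) guarding infeasible
prevalence/quota combinations.

What the generator does **not** emulate: genotyping error and missingness
(datasets are complete; QC and imputation are exercised on hand-built
fixtures instead), long-range LD and population structure, covariates, and
haplotype pools beyond a small template. Passing simulation checks
therefore says the statistic behaves as designed under clean,
moderately-LD'd two-gene data — not that it is robust to confounding in a
real cohort.

## Quality control

SNPs are dropped when the missing rate is ≥ 0.10, the MAF (over non-missing
entries) is ≤ 0.05 — both boundaries inclusive, matching the convention the
thresholds are quoted with — or the control-sample genotype counts violate
Hardy–Weinberg equilibrium at p < 1e-4. The HWE statistic is a 1-df
chi-square against the HWE-expected counts, switching to the exact
conditional test (probabilities summed over heterozygote counts no more
likely than the observed one) whenever an expected cell drops below 5; both
are exposed, chi-square being the default for the well-powered case.
Missing genotypes are represented as `NA` — never 0, which is a valid
genotype — and either mode-imputed per SNP or resolved by dropping
incomplete samples.

## Marker-level mining

After a gene pair tests positive, the unconstrained ensemble localises the
signal: for every edge from an internal node to an internal *child*, the
child's split gain accrues to the ordered (parent SNP, child SNP) pair and
its frequency increments. Only direct parent–child edges count — a
deliberate choice keeping the statistic interpretable as "SNP B refines SNP
A's split". The per-pair totals (`sumGain`) conserve gain exactly: pair
gains plus root gains equal the ensemble's total internal gain, which the
tests assert to 1e-6. Equal-width quartile bins over `[0, max sumGain]`
support heat-style displays, and same-gene pairs are reported alongside
cross-gene ones (a cross-gene-only filter exists) because within-gene
structure is informative about LD, not forbidden by the null.

## Sizes used in the package's own checks

The validation suite runs on one CPU, so the Monte-Carlo batteries use
reduced problem sizes chosen up front:

* type-I error: 50 null replicates (OR = 1, prevalence 0.01) at each of
  n = 1000 and n = 4000, m = 19 permutations, 20-tree ensembles — the
  permutation test's level is fidelity-free, so small ensembles are the
  efficient choice here; with m = 19, rejection at α = 0.05 is exactly
  "the observed statistic beats all 19 null draws";
* permutation-null uniformity: 120 null replicates at n = 300 against the
  uniform distribution (Kolmogorov–Smirnov at the 1% level);
* power: OR = 4, n = 4000, prevalence 0.01, 100-tree/10-fold fidelity,
  4 replicates per disease model;
* XOR detection: 20 seeds at n = 1000, m = 19.

## Known limitations

* The recessive–recessive model's signal — the double-minor-homozygote
  cell, population frequency $maf_1^2\,maf_2^2 \approx 0.1\text{–}3\%$ —
  sits at the cross-validation noise floor for reduced ensembles. The
  full-fidelity profile (1000 trees at rate 0.01, 10-fold CV, m ≈ 1000)
  recovers part of it but costs hours per power curve; at desk-scale
  fidelity, measured RR power is far below the full-fidelity figure. The
  dominant-style models do not share this fragility.
* Relative error amplifies noise when `err_orig` is small; the degenerate
  rules above keep the ordering well-defined, but very strong signals
  compress all permutation comparisons to `0 vs Inf`.
* p-values are multiples of 1/m: screening at α = 0.01 needs m ≥ 100, and
  Benjamini–Hochberg on permutation p-values with many exact zeros is
  conservative at best (the add-one estimator mitigates this).
* The test says *whether* genes interact, not *how*; the sumGain mining is
  descriptive, not inferential.
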