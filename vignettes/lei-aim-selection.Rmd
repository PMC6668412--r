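---
title: "LEI-based ancestry-informative marker selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LEI-based ancestry-informative marker selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `leikit`, the
design of its simulators, and the numerical and software choices made in
the implementation, including their known limitations.

## 1. The Lancaster estimator of independence

Consider one biallelic marker observed in `k` populations. Let `p` be
the 3 × k joint probability table over genotype classes
(0, 1, 2 copies of the counted allele) and population membership, with
row marginals `p_i.` and column marginals `p_.j`. The Lancaster
estimator of independence is the mean-square contingency

    theta^2 = sum_{i,j} p_ij^2 / (p_i. * p_.j) - 1.

Properties that the package's tests verify directly:

- `theta^2 = 0` if and only if genotype and population are independent
  (the table factorizes as `p_ij = p_i. * p_.j`).
- `0 <= theta^2 <= min(3, k) - 1`. The maximum is attained when each
  genotype class maps to a disjoint set of populations; for `k = 3`
  equal-sized populations with exclusive genotype classes the value is
  exactly 2.
- It is invariant under permutation of populations and under an allele
  flip (reversing the genotype rows).
- Cells whose row or column marginal is zero contribute 0; this is the
  continuous limit of the summand and keeps monomorphic markers and
  empty populations well defined.

Two estimators of the table are provided.

**LEI_Geno** (`lei_geno_scores`) fills the table with observed genotype
counts from labeled individuals, dropping missing genotypes marker-wise
(complete-case). It uses no distributional assumption but requires
individual-level data.

**LEI_Freq** (`lei_freq_scores`) requires only per-population allele
frequencies `f_j` and diploid sample counts `c_j` and fills the table
with Hardy–Weinberg expected counts

    n_0j = c_j (1 - f_j)^2,   n_1j = 2 c_j f_j (1 - f_j),   n_2j = c_j f_j^2.

Expected counts are kept fractional; rounding would break the algebraic
identity between the two estimators on exactly-HWE data. When genotype
counts are exactly at Hardy–Weinberg proportions, LEI_Geno and LEI_Freq
agree to machine precision; on Balding–Nichols panels their scores
correlate above 0.95 in the test suite. The HWE assumption is the main
limitation of LEI_Freq: markers under strong inbreeding or selection
within populations will be mis-scored relative to LEI_Geno.

## 2. Baseline rankers

- **Global F_ST** (`global_fst_scores`): the Nei heterozygosity
  partition `(H_T - H_S) / H_T` with `H_S` the `c_j`-weighted mean of
  `2 f_j (1 - f_j)` and `H_T = 2 fbar (1 - fbar)` at the weighted mean
  frequency. Markers with `H_T = 0` score 0.
- **PCA loadings** (`pca_scores`): the dosage matrix is column-centered
  (not variance-scaled, so rare markers are not inflated) and each
  marker is scored by `max(|a_1j|, |a_2j|)` over the first two principal
  axes. Eigenvector signs are canonicalized so serialized loadings are
  stable; scores are unaffected.
- **Random-forest Gini importance** (`rf_scores`): mean decrease in Gini
  impurity from a seeded 500-tree forest, normalized to sum to 1.
  Samples are processed in canonical (sorted-id) order so the result
  depends only on the data and the seed, not on input row order.
- **Linear SVM weights** (`svm_scores`): `k` one-vs-rest soft-margin
  linear classifiers; each marker is scored by the mean absolute
  hyperplane weight. Two numerical notes. First, the underlying solver
  (libsvm via `e1071`) fits the standard hinge loss; a squared-hinge
  formulation would shrink weights of margin violators slightly
  differently, but the ranking statistic is qualitatively identical and
  all documented symmetry and enrichment properties hold. Second, libsvm
  orients each hyperplane by order of label appearance, so the package
  canonicalizes every weight vector to point toward its target
  population; for `k = 2` the two weight vectors are then exact sign
  flips.

Missing dosages are mean-imputed per marker before PCA, RF and SVM,
since these methods cannot take `NA` predictors; LEI and F_ST handle
missingness natively.

## 3. Simulators

All synthetic data derive from **Balding–Nichols reference panels**
(`generate_reference_panels`): each marker draws an ancestral frequency
`p ~ U[0.05, 0.95]`, each population draws
`f ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance `p(1-p)F`), and
haplotypes are independent Bernoulli draws. Inter-marker spacing is
uniform on [500, 5000] bp. The drift parameter `F` plays the role of
F_ST. A calibration note: the plain Nei G_ST computed across `k`
populations systematically underestimates `F` — its expectation is
`F(1 - 1/k) / (1 - F/k)`, about 0.105 for `k = 3, F = 0.15` — so the
test suite checks generator calibration with the small-`k`-corrected
moment estimator (between-population variance with a `k - 1`
denominator), which is unbiased for `F`.

**Two-way admixture** (`simulate_two_way`) builds each chromosome as a
Poisson-switch mosaic: a chromosome-level ancestry probability
`theta ~ Beta(12, 3)` (mean 0.8), switch opportunities between adjacent
markers with probability `1 - exp(-g * d / 1e8)` for gap `d` bp and
`g = 8` generations since admixture, and segment ancestries drawn iid
Bernoulli(`theta`). 200 chromosomes are paired randomly into 100
individuals.

**Three-way admixture** (`simulate_three_way`) tiles each chromosome
with independent 100-kb blocks anchored at position 1; each block draws
its ancestry from the mixing proportions (default 0.6/0.3/0.1).

In both cases the reported truth `true_q` is the *realized* marker
fraction of each ancestry, not the drawn probability, and the full
provenance (chromosome-level probabilities, switch counts, source
haplotype choices, pairing) is recorded so that
`regenerate_genotypes` can rebuild every allele from the panels.

Realism limitations, by design: segment ancestries are iid rather than
Markov (no explicit recombination genealogy), blocks in the three-way
model are independent (no linkage between blocks), panels have no
linkage disequilibrium within populations, and there is no mutation or
genotyping error model. These simplifications keep every realized
quantity exactly computable, which is what the acceptance checks need.

## 4. Supervised ancestry estimation

`estimate_q` maximizes, for each individual with dosages `g_l` over `L'`
non-missing markers and known per-population frequencies `f_kl`, the
binomial log-likelihood

    sum_l [ g_l log(sum_k q_k f_kl) + (2 - g_l) log(sum_k q_k (1 - f_kl)) ]

by the multiplicative EM update

    q_k <- q_k / (2 L') * sum_l [ g_l f_kl / sum_m q_m f_ml
                                + (2 - g_l)(1 - f_kl) / sum_m q_m (1 - f_ml) ],

which is monotone in the log-likelihood and preserves the simplex.
Implementation choices:

- Frequencies are clamped to `[1e-6, 1 - 1e-6]` to avoid `log(0)` at
  fixed alleles.
- Initialization is uniform; the update is vectorized over individuals
  via matrix products, so 100 individuals × 20,000 markers converge in
  seconds.
- If every population has (numerically) identical frequencies the
  likelihood is flat; the estimator warns and returns uniform `q` with
  attribute `flat = TRUE` rather than an arbitrary interior point.
- Convergence is declared when the max change in `q` falls below `tol`
  (default 1e-6) or after `max_iter` iterations; the log-likelihood
  trace is returned for inspection.

Estimation is *supervised*: reference frequencies are taken as known
from the panels rather than re-estimated jointly. This removes
label-switching and makes subset-based estimates directly comparable,
at the cost of ignoring uncertainty in the reference frequencies.

Recovery error is summarized as RMSE — over one ancestry column in the
two-way case (`rmse_two_way`), pooled over all individuals and
ancestries in the multi-way case (`rmse_three_way`).

## 5. Evaluation utilities

`loocv_classify` runs leave-one-out cross-validation of a multinomial
logistic classifier (`nnet::multinom` with a small ridge penalty,
`decay = 1e-4`, for stability under separation) and reports the
confusion matrix, accuracy with an exact Clopper–Pearson 95% interval,
per-class one-vs-rest AUCs computed from confusion counts, and the
class-proportion-weighted mAUC. One behavior worth knowing: at chance
level (a marker independent of the labels), LOOCV accuracy is
*pessimistic*, not merely noisy — holding out a sample lowers its own
class's share among the training points, so near-uniform predictions
anti-correlate with the held-out label and accuracy falls below
`1/k`. Tests therefore bound chance-level accuracy from above rather
than asserting it equals `1/k`.

`topn_overlap` tabulates top-`N` membership patterns across rankers;
`q_correlations` reports Pearson correlations between ancestry estimates
with explicit flagging of zero-variance columns.

Rank ties are broken deterministically by genomic position and marker
id, so every ranking is reproducible byte for byte.

## 6. File formats

Plain text throughout: VCF v4.2 (reading via `vcfR`, writing via a
minimal GT-only emitter), a PLINK-style stratified frequency table
(`.frq.strat`, from which `c_j` is recovered as `NCHROBS / 2`, rounded
half up with a warning on odd counts), ADMIXTURE-style `.Q` matrices
(6 decimals by default, with a `digits` argument when lossless
round-trips are needed), TSV rankings, and TSV haplotype panels.

## 7. Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state afterwards. The command-line pipeline derives
per-stage seeds from one master seed via `derive_seed(seed, stage)`, so
inserting a stage never shifts the random stream of the others. The test
suite asserts bit-reproducibility of panels, cohorts and forests, and
byte-identity of all demo pipeline output files across runs.
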