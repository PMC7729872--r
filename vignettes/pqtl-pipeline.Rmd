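---
title: "Mapping protein quantitative trait loci with pqtlkit: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein quantitative trait loci with pqtlkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pqtlkit` implements a complete discovery-to-downstream analysis chain
for circulating-protein quantitative trait loci (pQTLs) in
whole-genome-sequenced cohorts, with the statistical features that
matter in small, isolated populations: cryptic relatedness, allele
frequency drift relative to reference panels, and an informative rare
tail of the site frequency spectrum. The chain is: NPX protein-panel
preparation, mixed-model single-variant scans, signal extraction and
approximate conditional/joint selection, functionally weighted
rare-variant burden tests, multiple-testing calibration, replication
assessment, two-sample Mendelian randomization (MR), and polygenic
score (PGS) construction and disease screening. A seeded synthetic
cohort generator with known truth underpins calibration studies and
every stochastic test the package ships.

# Phenotype preparation

Olink-style panels report natural-log Normalised Protein eXpression
(NPX), a relative quantification unit with a per-protein lower limit of
detection (LOD). Preparation follows the standard proteogenomics
recipe:

1. **LOD censoring** (`censor_below_lod()`): every entry strictly below
   its protein's LOD becomes missing.
2. **Protein exclusion** (`exclude_proteins()`): proteins whose
   missing-or-below-LOD proportion exceeds 40% (strictly) are dropped.
3. **Adjustment and transformation** (`adjust_and_transform()`):
   ordinary least squares on age, age squared, sex, plate indicators,
   season and the per-sample mean NPX, followed by an inverse-normal
   transform of the residual ranks with offset $(r - 0.5)/n$ and
   average ties.

Two choices deserve comment. First, the per-sample mean NPX — a
technical covariate capturing sample-level assay intensity — is
computed **leaving the focal protein out**. With hundreds of assays the
distinction is negligible, but this package must also behave sensibly
on small simulated panels, where including the protein in its own
covariate amounts to regressing it on itself and destroys genuine
signal; for single-protein panels the covariate is dropped entirely.
Second, season is encoded as a binary indicator (hot summer vs mild
winter); when plating follows collection order, plate and season are
strongly confounded, and aliased columns are dropped from the design
with a warning rather than failing the fit.

Post-transform phenotypes are marginally standard normal by
construction, which both stabilizes the mixed-model machinery and puts
effect sizes in phenotype-SD units.

# The linear mixed model scan

Per variant, the model is $y = W\alpha + g\beta + u + \varepsilon$ with
$u \sim N(0, \sigma_g^2 K)$ and
$\varepsilon \sim N(0, \sigma_e^2 I)$, where $K$ is the empirical
genetic relationship matrix (GRM) computed on an LD-pruned set of
variants with MAF > 1% passing the Hardy–Weinberg exact test at
$P \ge 10^{-5}$:
$K = m^{-1} \sum_j (g_j - 2f_j)(g_j - 2f_j)^\top / (2f_j(1 - f_j))$.

`reml_fit()` profiles everything but
$\lambda = \sigma_g^2/\sigma_e^2$ through the eigendecomposition of
$K$, brackets $\log\lambda$ on a decade grid over $[-5, 5]$ (base 10)
and finishes with Brent search; an identity-proportional $K$ is flagged
as unidentifiable (only the total variance is estimable then, which
the object reports). `score_scan()` then computes, per variant, the
score statistic $(g^\top P y)^2 / (g^\top P g)$ with
$P = V^{-1} - V^{-1}W(W^\top V^{-1}W)^{-1}W^\top V^{-1}$ and
$V = \hat\sigma_g^2 K + \hat\sigma_e^2 I$, referred to the upper tail
of $\chi^2_1$; the reported effect and standard error are the
equivalent generalized-least-squares quantities, so effect sizes are
per-allele in phenotype-SD units. Variant filters: minor allele count
$\ge 10$ and missingness $\le 1\%$; missing dosages are mean-imputed
per variant, keeping $n$ constant (common mixed-model GWAS practice).
Per-trait calibration is gated by genomic control:
$\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549$, accepted in
$[0.97, 1.05]$.

# Signal extraction and conditional/joint selection

`extract_signals()` implements distance-and-LD peak calling: variants
passing the significance threshold are sorted by increasing p-value;
each retained variant removes all remaining significant variants with
$r^2 > 0.2$ (computed from in-sample dosages); retained variants
within less than 2 Mb of each other (transitive chaining, exposed as a
parameter because very large peaks in long-range LD may need manual
merging) group into one signal whose index is the lowest-p member.
P-value ties break by genomic position, lower first.

`cojo_select()` performs approximate conditional and joint stepwise
selection from summary statistics: with $D_j = 2f_j(1-f_j)n_j$ and $R$
the in-sample dosage correlation, the normal equations use
$X^\top X \approx D^{1/2} R D^{1/2}$ and $X^\top y_j = D_j\hat\beta_j$;
$y^\top y$ is taken as the median over variants of
$D_j\hat\beta_j^2 + D_j s_j^2 (n_j - 1)$. Forward steps add the
candidate with the smallest conditional p (candidates with $r^2 > 0.9$
against the selected set are skipped and logged); backward steps drop
any selected variant whose joint p exceeds the threshold; the loop
runs to a fixed point. `clump()` (greedy by ascending p, $r^2 > 0.1$
within 1 Mb) precedes selection when many predictors threaten
overfitting. `conditional_scan()` reuses the same joint algebra to
re-test every variant conditional on a fixed set, reporting p = 1 for
targets that are near-proxies ($r^2 > 0.9$) of the conditioning set.
The effective $n$ per variant is its non-missing count. The joint
estimates agree with exact multiple regression on raw dosages to
within 10% on LD-structured test data.

# Rare-variant burden testing

`build_masks()` assembles four weighting schemes per gene from the
annotation table, after rare-variant filters (MAF < 5%, missingness
< 1%, both strict): protein-truncating/splice variants
("severe", unit weights; consequence strictly more severe than
missense, with an `include_missense` switch because that reading is
ambiguous), all coding variants weighted by CADD-like phred scores,
coding plus gene-linked regulatory variants weighted by Eigen-like
phred scores, and regulatory-only with Eigen weights. Regulatory
variants link to a gene through annotated eQTL-bearing regulatory
regions. Phred weights are used raw, with no extra MAF-based beta
weighting (the weighting the source software applies internally is not
documented, so nothing is stacked on top), and the statistic's p-value
is invariant to rescaling all weights.

`skato_lmm()` computes the optimal unified burden/variance-component
test on mixed-model-decorrelated residuals: genotypes and phenotype
are rotated by $V^{-1/2}$, projected orthogonally to the covariates,
weighted, and combined as
$Q_\rho = (1-\rho)\sum_j w_j^2 S_j^2 + \rho(\sum_j w_j S_j)^2$ over
the grid $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ (the
original optimal-test grid). Each $Q_\rho$ is a quadratic form in
normals whose null distribution is evaluated by Imhof's
characteristic-function inversion in the tail and the Liu four-moment
approximation in the bulk, where the oscillatory integral converges
slowly and the moment approximation is accurate far beyond practical
tolerance; a failed integration falls back to the moment
approximation and is flagged. The overall p-value combines the grid
minimum through the one-dimensional integration over the shared
burden component, with the variance inflation term for the
cross-correlation between the burden direction and the residual
variance-component part. A 100,000-permutation oracle on a 5-variant
mask agrees with the analytic p within Monte-Carlo error, and the
empirical size at $\alpha = 0.05$ under cryptic relatedness sits
inside $[0.035, 0.065]$ over 2000 null simulations.

`conditional_burden()` adds the dosage of the most significant
single-point variant inside the mask to the fixed covariates and
re-tests the remaining members, so surviving signals require at least
two distinct contributing variants — the same guard the discovery
analysis applies before declaring a rare-variant pQTL.
`burden_meta()` combines cohorts by $\sqrt{n}$-weighted Stouffer on
one-sided z-equivalents; gene/scheme pairs present in one cohort only
are carried through flagged.

# Multiple-testing calibration

The effective number of traits uses the eigenvalue-variance form
$M_{\mathrm{eff}} = M\,(1 - (M-1)V_{\lambda}/M^2)$ with $V_\lambda$
the population variance of the trait-correlation eigenvalues: identity
correlation returns $M$; two perfectly correlated traits return 1.5.
Study-wide thresholds are
$\alpha / (M_{\mathrm{eff}} \times n_{\mathrm{eff,variants}})$, with
the variant-side effective count supplied by the user or estimated by
`combined_test_inflation()`: over null-phenotype replicates, the
minimum p across the single-point scan, the burden scan, or both is
recorded, and the effective count for each reporting scheme is
$\alpha$ divided by the empirical $\alpha$-quantile of the minima. On
the package's desk-scale configuration (500 samples, 20,000 variants,
100 genes with four masks each, 200 replicates — chosen as the
standard calibration size for this package) the combined-to-single
ratio stays below one order of magnitude, consistent with burden tests
adding only a few hundred heavily correlated tests to tens of
thousands of single-point ones.

Replication calls use a fixed threshold $0.05/N_{\mathrm{variants}}$
(strict inequality), map discovery variants to themselves or their best
$r^2 > 0.8$ tag in the replication table, require directional
consistency by default (the natural reading of replication, exposed as
a switch), and report variants that are absent or monomorphic in
replication as unassessable rather than failed. The one-sided
one-sample proportion test for allele-frequency-increase counts is the
normal approximation without continuity correction — which reproduces
the printed 0.002 for 53 increases out of 80, where the exact binomial
gives ≈0.003 — and two-population frequency comparisons use the
two-proportion z-test with fold-change and >5-fold flags.

# Mendelian randomization

Instruments are the conditionally independent variants of each
protein's joint model. `assemble_instruments()` matches them into an
outcome GWAS by id, falling back to the best $r^2 > 0.8$ tag (ties by
distance, effects sign-flipped on negative LD), harmonizes effect
alleles (sign flips on ref/alt swaps), drops instruments in excluded
pleiotropic loci, and by default drops palindromic variants with
MAF > 0.42 — a standard harmonization safeguard, switchable because
the synthetic data never needs it. Single-instrument proteins use the
Wald ratio $\hat\theta = \hat\beta_{\mathrm{out}}/\hat\beta_{\mathrm{exp}}$
with the first-order standard error
$s_{\mathrm{out}}/|\hat\beta_{\mathrm{exp}}|$; multi-instrument
proteins use fixed-effect inverse-variance weighting of the
per-instrument ratios, algebraically the zero-intercept weighted
regression of outcome on exposure effects. No pleiotropy-robust
estimators (MR-Egger, weighted median) are provided: with at most a
handful of instruments per protein they are underpowered to the point
of being uninformative, which is exactly the regime this design
targets. Screening across protein-outcome pairs controls FDR by
Benjamini–Hochberg at 0.05 and flags "actionable" pairs where a
significant positive causal estimate coincides with a level-lowering
instrument allele — the allele that lowers the protein also lowers
disease risk. Coverage of the 95% interval for planted effects is
within [90%, 99%] across simulation seeds.

# Polygenic scores

`fit_scores()` is clumping + thresholding: greedy LD clumping
($r^2 = 0.1$, 1 Mb), then every combination of a p-value threshold and
a MAF rule (MAF ≥ 0.05, MAF ≥ 0.01, or MAC ≥ 10) defines a weight set
from the discovery effect sizes. The threshold grid is log-spaced
between $10^{-4}$ and the study-wide threshold — a linear grid with a
$10^{-10}$ step is degenerate near $10^{-4}$, so log spacing is this
package's interpretation of "assess scores between the two bounds".
Scores are $\sum_j \hat\beta_j \cdot \mathrm{dosage}_{ij}$ with missing
dosages imputed from discovery allele frequencies; scoring is linear in
the dosage matrix. Validation r² is the squared Pearson correlation
with the prepared phenotype in an independent cohort, maximized over
the grid per protein; repeated 5-fold cross-validation with a 20%
hold-out guards the grid optimization against overfitting and reports
rank stability. Disease screening fits per protein-phenotype logistic
regressions of binary labels on the standardized score plus clinical
covariates, flags Wald p-values against
$\alpha/(n_{\mathrm{proteins}} \times n_{\mathrm{eff,phenotypes}})$
(the effective phenotype count is an input — its derivation depends on
phenotype data the package does not model), detects separation, and
model comparison reports the likelihood-ratio test on the deviance
difference together with DeLong's paired test on the AUC difference
(structural-components estimator, half credit for ties, p = 1 for
identical classifiers). `elastic_net_select()` validates manual
variable selection: penalized logistic fits over the mixing grid
$\alpha \in \{0, 0.1, \ldots, 1\}$, penalty tuned per $\alpha$ by
cross-validated deviance at `lambda.1se` — the "one standard error
above the minimum" rule, which is how the "one standard deviation from
the minimal value" prescription is realized — with covariates
unpenalized and hold-out AUC reported per $\alpha$.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults define the
study conditions for every calibration result above.

**LD-structured genotypes.** `simulate_haplotypes()` builds a founder
pool in independent blocks by mosaic copying from a small template set
with a per-site switch probability (default 0.08), so within-block r²
decays with distance and across-block r² is zero in expectation — a
deliberately simple copying model with tunable LD, not a coalescent.
Generating frequencies follow a Beta(0.25, 1.4) spectrum; sites rarer
than 5% are drawn independently on the pool haplotypes because
template copying quantizes frequencies at one over the template count
and would otherwise leave no genuinely rare variation. The realized
pool frequencies serve as the "reference panel" truth.

**Isolate drift.** `simulate_cohort()` perturbs reference frequencies
by a Balding–Nichols Beta draw with parameter $F$:
$E(p') = p$, $\mathrm{Var}(p') = F\,p(1-p)$ — a testable closed form
that reproduces the qualitative isolate phenomenon of strongly
enriched alleles. Cohort haplotypes are fresh mosaics of the pool
(binomial sampling around pool frequencies at $F = 0$), with per-entry
allele flips moving each site to its drifted frequency while
preserving the copying LD structure as far as possible.

**Relatedness.** Families are full-sib pairs: four parental haplotypes
per family, whole-block transmission, pedigree expectation 0.5 in the
GRM entry (verified empirically within ±0.05 at genome scale).
Missingness is injected independently per genotype.

**Proteins.** Each protein is covariates + per-allele genetic effects
(cis, trans, rare-burden) + a polygenic term
$N(0, h^2_{\mathrm{poly}} K_{\mathrm{truth}})$ + noise, on an NPX-like
scale with an arbitrary baseline; a variance budget
($\sum \beta^2 2f(1-f) + h^2 \le 1$) is enforced, and the noise SD
defaults to completing the budget to 1. The LOD is the empirical
`lod_quantile` of each protein's values, reproducing the censoring
mechanism (the real LOD is assay-derived; a quantile is the faithful
emulation when no assay noise floor exists). Plate shifts are random
per-plate intercepts; season is confounded with plate by construction
(plating in collection order).

**What is not emulated.** Realistic human LD maps and recombination
hotspots, demographic history, sequencing reads, genotype likelihoods
and phasing, assay-specific LOD chemistry, batch drift over time, and
epitope artefacts of protein-altering variants. Passing tests
therefore demonstrate statistical correctness and calibration of the
methods under the stated generative assumptions — not robustness to
everything real cohorts can contain.

# Numerical choices and degenerate inputs

- REML: Brent on $\log\lambda \in [-5, 5]$ decades after a grid
  bracket; boundary solutions at $\lambda \to 0$ are accepted;
  identity GRMs are flagged unidentifiable.
- Quadratic forms: Imhof inversion (`integrate`, rel.tol $10^{-9}$)
  below Liu-p 0.1, Liu elsewhere; mixtures reduced to their dominant
  eigenvalues at relative tolerance $10^{-10}$; p-values clamped to
  $[10^{-14}, 1]$.
- Ties: p-value ties in peak calling and clumping break by position;
  PGS tag ties by distance; rank ties in the inverse-normal transform
  by averaging.
- Zero-variance dosages are skipped and logged in scans; constant
  scores report r² = 0 flagged; empty PGS models are valid empty
  results, not errors; monomorphic genotype counts give HWE p = 1.
- Separation in logistic screens is detected (fitted probabilities at
  the boundary or runaway coefficients) and excluded from
  significance flags.
- All randomness flows through explicit integer seeds; cohort
  generation, cross-validation and the acceptance script are
  reproducible bit-for-bit at a fixed seed.

# Problem sizes used by the shipped checks

The test suite exercises cohorts of 250–1300 samples and 200–8000
variants, with the combined-test inflation study at 400 samples, 8000
variants, 40 genes and 150 null replicates; the acceptance script runs
the inflation study at 500 samples, 20,000 variants, 100 genes and 200
replicates, heritability recovery over 20 seeds at n = 600, the
planted rare-cis recovery at n = 1300, MR recovery over 100 outcome
draws at n = 2000, and test-size checks over 2000 null simulations.
These sizes are the package's standard calibration configuration:
large enough for the bands checked (Monte-Carlo standard errors well
inside each band), small enough to run on a laptop core.

# Known limitations

- In-sample LD is used both for discovery pruning and as the COJO
  reference; external-panel LD mismatch is out of scope.
- The mixed model fits variance components once per trait (null
  model), not per variant; this is the standard score-test shortcut
  and can leave slight proximal contamination around very strong
  signals (no leave-one-chromosome-out option yet).
- The burden meta-analysis is a p-value combination, not a joint
  variance-component analysis.
- Binary-trait burden testing, X-chromosome dosage compensation,
  dominance terms and multi-trait models are not implemented.
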