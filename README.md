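# pqtlkit

Protein quantitative trait locus (pQTL) discovery, calibration and
downstream inference for whole-genome-sequenced cohorts — built for the
setting where isolated populations, cryptic relatedness and rare
variation do the heavy lifting.

Circulating protein levels sit between genome and disease: mapping the
variants that control them identifies biomarkers and drug-target
candidates, and their genetic scores let biobanks without proteomics
impute protein levels and correlate them with disease. `pqtlkit`
implements that entire analysis chain as composable, tibble-first R
functions, together with a seeded synthetic-cohort generator with known
truth so that every statistical claim the package makes is testable.

## What it computes

For protein level $y$ (Olink-style NPX, LOD-censored, covariate-adjusted
and inverse-normal transformed) the single-variant model is the linear
mixed model

$$y = W\alpha + g\beta + u + \varepsilon,\qquad
  u \sim N(0, \sigma_g^2 K),\quad \varepsilon \sim N(0, \sigma_e^2 I),$$

with $K$ an empirical genetic relationship matrix on LD-pruned common
variants, $\sigma^2$-components estimated by REML, and per-variant score
tests $(g^\top P y)^2/(g^\top P g) \sim \chi^2_1$. On top of the scan:

- **Signal extraction** (sort by p, prune at $r^2 > 0.2$, group within
  2 Mb) and **approximate conditional/joint stepwise selection** from
  summary statistics via $X^\top X \approx D^{1/2} R D^{1/2}$,
  $D_j = 2f_j(1-f_j)n_j$;
- **Rare-variant burdens**: SKAT-O under the mixed model,
  $Q_\rho = (1-\rho)\sum w_j^2 S_j^2 + \rho(\sum w_j S_j)^2$, with four
  functional masks (severe consequence, CADD-weighted coding,
  Eigen-weighted coding+regulatory, Eigen-weighted regulatory-only) and
  conditional re-testing on the top single-point variant;
- **Calibration**: effective trait count
  $M_\mathrm{eff} = M(1-(M-1)V_\lambda/M^2)$ from the eigenvalue
  variance of the trait correlation matrix, simulation-based effective
  test counts for combined single-point + burden reporting, genomic
  control, replication thresholds $0.05/N$, BH-FDR, allele-frequency
  divergence statistics;
- **Two-sample MR**: Wald ratio / fixed-effect IVW on harmonized
  conditionally independent instruments, with tagging proxies at
  $r^2 > 0.8$ and pleiotropic-locus exclusion;
- **Polygenic scores**: clumping + p-value thresholding over MAF rules,
  independent-cohort validation $r^2$, repeated cross-validation,
  logistic disease screening with LRT/DeLong model comparison, and
  elastic-net score selection.

## Worked example

`pipeline_demo_run()` generates a full synthetic study — a discovery
cohort with 60 sib-pair families and allele-frequency drift, an
independent replication cohort, and an independent outcome cohort —
plants three signal classes (a common cis variant, a common trans
variant, a two-variant rare burden in one gene) and runs the whole
chain:

```r
library(pqtlkit)
run <- pipeline_demo_run(seed = 2024)
```

```
study-wide threshold : 1.15e-05 (M_eff = 6.00)
lambda_GC (cis trait): 0.985
cis signal found/selected : TRUE / TRUE
trans signal found/selected: TRUE / TRUE
burden: scheme coding_cadd, p = 1.26e-16, conditional p = 1.09e-09
cis replication: replicated
MR estimate (true 0.4): 0.363 +/- 0.078 (q = 2.8e-06)
best validation PGS r2: 0.093
```

Reading this: the per-trait scans are well calibrated
($\lambda_{GC} = 0.985$); both planted common variants are recovered as
signals and survive joint selection (the cis variant's joint effect,
`run$tables$joint_cis`, is 0.503 ± 0.056 against a planted 0.5); the
rare burden is study-wide significant under the CADD-weighted coding
mask and remains so after conditioning on its best single variant,
i.e. at least two distinct rare variants drive it; the cis variant
replicates in the independent cohort; the causal protein-on-outcome
effect is recovered by MR within one standard error of the planted 0.4;
and the protein's polygenic score transfers to the validation cohort
with $r^2 = 0.093$. Every stage's full table is in `run$tables`.

Individual stages are ordinary functions over tibbles and plain
matrices — `censor_below_lod()`, `adjust_and_transform()`,
`compute_grm()`, `reml_fit()`, `score_scan()`, `extract_signals()`,
`cojo_select()`, `burden_scan()`, `replication_assess()`,
`mr_screen()`, `fit_scores()` … — with `tidy()`/`glance()` methods on
fitted objects and `autoplot()` for Manhattan plots. See the vignette
(`vignettes/pqtl-pipeline.Rmd`) for the models, assumptions and design
decisions.

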