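# gcgwas — multi-trait GWAS for growth-curve parameters

Beef-cattle growth is a longitudinal trait: each animal is weighed
repeatedly (here at 0, 6, 12, 15, 18 and 24 months) and the whole
trajectory, not the weight at any one age, is what breeding programs want
to shape. `gcgwas` implements the growth-curve GWAS workflow for that
setting:

1. **Growth-curve fitting.** Five classical nonlinear models are fitted
   per animal by Gauss–Newton/Levenberg–Marquardt least squares —
   Brody `w_t = A(1 − b·e^{−Kt})`, von Bertalanffy
   `w_t = A(1 − b·e^{−Kt})³`, Logistic `w_t = A(1 + b·e^{−Kt})^{−1}`,
   Gompertz `w_t = A·e^{−b·e^{−Kt}}` and Richards
   `w_t = A(1 ± b·e^{−Kt})^M` — where `A` is the mature (asymptotic)
   weight in kg, `K` the maturity rate (reciprocal of the age unit) and
   `b` the integration constant fixing the curve at age zero. Models are
   compared on convergence rate C%, adjusted R², MSE, MAD over the early
   and late curve segments, and AIC. Raw weights can first be pre-adjusted
   for fixed effects (contemporary group, birth date, farm) by per-age OLS.
2. **Multi-trait mixed-model GWAS.** The per-animal estimates
   `(Â, b̂, K̂)` become a three-trait phenotype in the animal model
   `Y = Ws + Zu + e`, with `u ~ N(0, Σu ⊗ A)` a polygenic effect
   structured by the pedigree numerator relationship matrix `A`
   (Henderson's tabular method) and `e ~ N(0, Σe ⊗ I)`. `Σu`, `Σe` are
   estimated once by eigendecomposition-accelerated multivariate EM-REML —
   giving heritabilities `h²` and genetic correlations `r_g` — and each
   SNP is then tested by generalized least squares with the variance
   components held fixed (two-stage scan). Benjamini–Hochberg controls
   the FDR; per-SNP variance shares are
   `V_i = 100·2p_i q_i ŝ_i² / Σ_j 2p_j q_j ŝ_j²`.
3. **LD blocks, annotation, validation.** Gabriel-style haplotype blocks
   (two-locus EM haplotype frequencies, likelihood-profile D′ confidence
   intervals) aggregate `V_i` over members; significant SNPs are annotated
   against a local BED gene table (1 Mb rule); and a full synthetic-data
   generator (full-sib families, Haldane recombination, planted QTL,
   pedigree-structured polygenic covariance) supports genotype QC checks,
   type-I-error and QTL-detection-power studies.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
populations whose defaults emulate the target cattle cohort (1,255
animals, 251 full-sib families, Brody growth, residual SD 19.6 kg) and a
multi-family validation design (100 families × 20 offspring, 453 SNPs on
5 chromosomes of 1 Morgan, 6 QTL per parameter):

```sh
Rscript analysis/01_simulate.R     # writes results/data/
Rscript analysis/02_fit_growth.R   # five-model comparison + per-animal fits
Rscript analysis/03_gwas.R         # REML, genetic parameters, SNP scan
Rscript analysis/04_blocks.R       # LD blocks + synthetic gene annotation
Rscript analysis/05_power.R        # 10-replicate detection-power study
```

`02_fit_growth.R` prints the model comparison (this run's output):

```
  model        C%    r2_adj   mse     mad1   mad2   aic    criteria_won rank
  brody        93.4  0.972    385.4    9.5   11.5   37.3   5            1
  bertalanffy  90.7  0.970    447.8   11.4   12.1   38.2   0            2
  gompertz     94.7  0.965    527.6   13.1   12.7   39.3   0            3
  logistic     91.2  0.951    813.7   18.1   14.4   42.1   0            4
selected model: brody
```

Brody wins all five criteria (Richards is excluded beforehand for a
convergence rate below 50%), and its mean MSE ≈ 385 kg² matches the
19.6 kg residual SD the cohort was generated with. `03_gwas.R` then
reports the genetic parameters of the validation population
(parameter-level h² of 0.3 was planted for each trait):

```
h2: 0.437 / 0.303 / 0.315
rg (A-b, A-K, b-K): 0.141 / -0.265 / 0.014
```

and `05_power.R` the detection power over 10 phenotype replicates, with a
within-timepoint permutation replicate as the null reference:

```
  param large_pct small_pct
  A     100       4
  b     100       0
  K     100       0        (permuted null: 0 everywhere)
```

The large-effect QTL (1 genetic SD) is found in every replicate for every
parameter; the small ones (0.2 SD) are rarely genome-wide significant at
this sample size, and the permuted data — which destroy the
genotype–phenotype link while keeping each time point's marginal
distribution — yield no detections at all.

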