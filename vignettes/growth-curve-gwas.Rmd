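---
title: "Growth-curve parameter GWAS: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve parameter GWAS: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what is modelled, which knobs matter, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## 1. The two-stage model

The phenotype of interest is the shape of an animal's weight–age
trajectory, summarised by the parameters of a nonlinear growth function.
Stage one fits, per animal, one of five classical models (Brody, von
Bertalanffy, Logistic, Gompertz, Richards; see `growth_model()`), each
parameterised by the mature weight $A$ (kg), the integration constant $b$
(unitless) and the maturity rate $K$ (per age unit; Richards adds the
inflection exponent $M$). Residuals within an animal are treated as
independent and homoscedastic — the comparison of within-animal
correlation structures is out of scope here, and the independence
structure is the one this pipeline implements throughout.

Stage two treats the per-animal estimates $(\hat A,\hat b,\hat K)$ as a
three-trait phenotype in the animal model
$$\mathbf{Y} = \mathbf{W}\mathbf{s} + \mathbf{Z}\mathbf{u} + \mathbf{e},
\qquad \mathbf{u} \sim N(0, \Sigma_u \otimes \mathbf{A}),
\qquad \mathbf{e} \sim N(0, \Sigma_e \otimes \mathbf{I}),$$
where $\mathbf{A}$ is the pedigree numerator relationship matrix and
$\mathbf{W}$ holds one SNP's 0/1/2 allele dosages. Heritabilities and
genetic correlations come from $\Sigma_u, \Sigma_e$; the per-SNP effect
vector $\hat{\mathbf{s}} = (\hat s_A, \hat s_b, \hat s_K)$ is tested per
trait (Wald, normal reference — with roughly a thousand phenotyped
animals and fixed variance components the $t$ correction is negligible)
and jointly (3-df chi-square).

### Per-animal least squares, deliberately

The curve parameters are estimated by *independent* per-animal least
squares rather than a population-deviation nonlinear mixed model. With
six observations for three parameters the shrinkage a mixed fit would add
is modest for well-conditioned animals, and the independent fit keeps the
stage-one/stage-two separation clean and testable. The cost is fit noise:
linearising the Brody model at the cohort means ($A=520$, $b=0.92$,
$K=0.06$/month, residual SD 19.6 kg over ages 0–24 months) gives
per-animal estimation SDs of roughly ±86 kg for $\hat A$, ±0.034 for
$\hat b$ and ±0.020 for $\hat K$ — for $b$ and $K$ this is as large as or
larger than the plausible biological spread. Estimation noise loads on
$\Sigma_e$, so heritabilities measured on noisy estimates are attenuated
relative to the parameter-level values. This is a property of the design,
not a bug; the acceptance checks therefore validate the genetic machinery
on noise-free cohorts (where $\hat\theta \equiv \theta$ to $10^{-10}$)
and document the attenuation on noisy ones.

## 2. Numerical choices

* **Curve fitting.** Gauss–Newton with a Levenberg–Marquardt damping
  ladder (×10 per rejected step), analytic Jacobians, convergence at
  relative parameter change $<10^{-8}$ within 200 iterations. Starting
  values: $A_0 = 1.1\max w$, $b_0$ solved from the first record, $K_0$ a
  grid argmin over $\{0.005,\dots,0.5\}$; non-growing series fall back to
  $A_0=\max w$ with a warning. A fit pinned at the $b$ floor has
  degenerated to a constant curve and is counted as non-converged. The
  test suite cross-checks against `minpack.lm::nlsLM`.
* **Goodness of fit.** $MSE = SSE/(n-p)$; adjusted
  $R^2 = 1 - \frac{SSE/(n-p)}{SST/(n-1)}$;
  $AIC = n\log(SSE/n) + 2(p+1)$ with $SSE$ floored at $10^{-12}$ so a
  perfect fit stays finite; MAD over the early/late curve segments split
  at the median age (0–12 vs 15–24 months on the cattle grid). Model
  selection counts outright wins on five criteria after dropping models
  with C% < 50 (Richards routinely lands there on 6-point data), ties
  broken by mean AIC.
* **REML.** The phenotyped-subset relationship matrix is eigendecomposed
  once; rotating the phenotypes factorises the restricted likelihood over
  eigenvalues into $3\times3$ problems. EM-REML updates (with the
  fixed-effect uncertainty term, so the restricted likelihood is
  monotone) run to a log-likelihood change $<10^{-8}$; a doubled
  extrapolation step is tried each iteration and kept only when it
  improves the likelihood, which preserves monotonicity while roughly
  halving iteration counts. A full average-information Hessian step was
  rejected because it is not monotone and the monotonicity invariant is
  asserted in the tests. Traits are standardised to unit variance
  internally — the EM is scale-equivariant in exact arithmetic, but kg²
  next to (per-month)² spans nine orders of magnitude and wrecks the
  $3\times3$ solves in floating point — and the components are mapped
  back afterwards. Estimates are projected onto the PSD cone (eigenvalue
  clipping) with a flag whenever projection changed anything. Typical
  iteration counts are a few hundred; near-boundary problems may need a
  few thousand, so the `max_iter` default of 500 marks such runs
  `converged = FALSE` and callers that care pass a higher cap.
* **Scan.** Variance components are estimated once under the null and
  held fixed for every SNP (the standard two-stage approximation; a
  per-SNP REML refit would cost three orders of magnitude more and moves
  third-decimal digits). Missing genotypes are mean-imputed inside the
  scan only; QC keeps missingness explicit. SNPs constant after
  imputation are flagged untestable rather than dropped.
* **HWE exact test.** Two-sided exact p by log-space recurrence over
  heterozygote counts; a brute-force enumeration oracle backs it in the
  tests.
* **LD.** Two-locus haplotype EM (double heterozygotes split by phase
  probabilities, tolerance $10^{-10}$); D′ confidence intervals by
  normalised likelihood profile over a 201-point D′ grid with allele
  frequencies held at their estimates — the construction used by
  Gabriel-style block callers. Blocks require the D′ CI bounds
  (0.70, 0.98), strong-recombination cutoff 0.90 and ≥95% strong-LD
  informative pairs; maximal non-overlapping candidates are chosen
  greedily by span, ties to the left, never across chromosomes.

## 3. What the generator emulates — and what it does not

`sim_preset("brahman_like")` encodes the cattle-cohort conditions: 251
full-sib families × 5 offspring (1,255 phenotyped), Brody means
$(520.32, 0.92, 0.06)$, weight residual SD $\sqrt{382.79}=19.57$ kg,
parameter-level heritabilities $(0.23, 0.41, 0.31)$ and genetic
correlations $(0.78, -0.84, -0.88)$ for $(A,b)$, $(A,K)$, $(b,K)$. True
total parameter SDs are $(139.1, 0.02, 0.012)$: the $A$ spread was chosen
so that, once the ±86 kg per-animal fit error is added, $\hat A$ shows a
total SD near 164 kg, while $b$ and $K$ use plausible biological spreads
(their target-scale totals are already saturated by fit error under
per-animal least squares, so they cannot be matched exactly — see §1).

`sim_preset("qtlmas2009")` encodes the validation design: 100 full-sib
families × 20 offspring with half of each family phenotyped and genotyped
(1,000 scanned animals), 453 SNPs evenly spaced over 5 chromosomes of
1 Morgan (Haldane map function, no interference, 1 cM drawn as 1 Mb),
logistic growth at days 0, 132, 265, 397, 530 — the third time point read
as 265 for even ~132-day spacing — population means $(500, 9, 0.012)$,
weight residual SD 5, parameter-level $h^2 = 0.3$ per trait, and per
parameter six QTL planted on existing SNPs: one large (1.0 polygenic SD)
and five small (0.2 SD). The exact positions and effects of the original
original external dataset are not available here, so the preset is parametric, not a
replica; its detection percentages are comparable in kind, not digit by
digit. In particular the 0.2-SD small QTL sit near the detection floor at
$n=1000$, so small-QTL power lands in single digits here.

Deliberately **not** emulated: founder linkage disequilibrium (founder
haplotypes are drawn independently per SNP, so LD exists only through
family co-segregation — which is why Gabriel blocks are usually empty on
this preset and the block caller is validated on constructed
perfect-LD fixtures instead), selection, overlapping generations,
genotyping error, age-heteroscedastic residuals (the i.i.d. residual
cannot reproduce a 5 kg birth-weight SD next to a 34 kg SD at 24 months),
and X-specific dosage (chromosome labels are opaque strings).

### Replicates and the permutation scheme

The validation replicates keep the genotypes and planted QTL fixed and
redraw the polygenic and residual terms — fresh phenotype realisations of
the same base population. A within-timepoint record permutation
(`permute_within_timepoint()`) is implemented and tested as well, but as
a *null* device: shuffling records across animals at each time point
preserves every time point's marginal distribution and the sigmoid shape
of each reassembled trajectory while severing both the across-age
dependence and the genotype–phenotype link, so a scan on permuted data
measures false positives, not power. Treating permuted datasets as power
replicates would be internally contradictory, which is why the power
study uses redrawn phenotypes and reports the permuted run separately as
its null reference.

## 4. Problem sizes and determinism

All data are generated at run time; the test suite and the acceptance
script run in a few minutes on one CPU at the study scales: 1,255 animals
for curve fitting (about 8 s for one model), REML at $n$ = 1,000–1,255
(seconds per fit after the one-off eigendecomposition), 453-SNP scans
(< 1 s), 10-replicate power and type-I studies. Every stochastic step
takes an explicit integer seed, and the acceptance script derives all of
its seeds from the single `--seed` argument, so runs are exactly
reproducible.

## 5. Known limitations

* Heritabilities measured on noisy per-animal estimates are attenuated
  (§1); only the noise-free pipeline recovers the planted values, and
  real-data applications would want either shrunken stage-one estimates
  or an errors-in-variables stage two.
* The FDR rule (BH $q<0.05$) and the raw $p<0.001$ rule are reported side
  by side; the package never combines them silently, since reasonable
  pipelines differ on whether the second is a filter or an alternative.
* `bh_fdr()` applied to its own q-values is *not* idempotent in the
  significance set (q-values are not p-values); re-running the procedure
  on q-values is therefore rejected in code review rather than supported.
* The D′ confidence interval uses the likelihood profile only; a
  bootstrap fallback for degenerate profiles was considered and dropped —
  degenerate pairs (monomorphic, too few informative genotypes) are
  returned flagged instead.
* Dense relationship matrices cap practical pedigrees at a few tens of
  thousands of animals; sparse-inverse methods are out of scope.
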