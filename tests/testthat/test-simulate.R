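small_cfg <- function(...) {
  args <- utils::modifyList(list(
    n_families = 30, offspring_per_family = 8, n_snps = 40,
    n_chromosomes = 2, time_points = c(0, 6, 12, 15, 18, 24),
    curve_model = "brody", population_params = c(A = 500, b = 0.9, K = 0.07),
    qtl_per_param = 0, polygenic_cov = diag(c(100, 4e-4, 1e-4)),
    param_env_cov = diag(c(300, 1.2e-3, 3e-4)), residual_sd = 5), list(...))
  do.call(sim_config, args)
}

test_that("family simulation has the configured shape and is reproducible", {
  cfg <- small_cfg()
  fam1 <- simulate_families(cfg, 81)
  fam2 <- simulate_families(cfg, 81)
  expect_identical(fam1$geno$codes, fam2$geno$codes)
  expect_identical(as.data.frame(fam1$ped), as.data.frame(fam2$ped))
  fam3 <- simulate_families(cfg, 82)
  expect_false(identical(fam1$geno$codes, fam3$geno$codes))
  # 2 parents per family + offspring, all genotyped
  expect_equal(nrow(fam1$ped), 30 * 2 + 30 * 8)
  expect_equal(nrow(fam1$geno$codes), 30 * 2 + 30 * 8)
  founders <- is.na(fam1$ped$sire) & is.na(fam1$ped$dam)
  expect_equal(sum(founders), 60L)
  expect_equal(length(unique(fam1$geno$map$chrom)), 2L)
  expect_error(simulate_families(small_cfg(n_snps = 1, n_chromosomes = 2), 1),
               "n_snps")
})

test_that("offspring allele frequencies track founder frequencies", {
  cfg <- small_cfg(n_families = 60, offspring_per_family = 10)
  fam <- simulate_families(cfg, 83)
  off <- fam$ped$animal[!is.na(fam$ped$sire)]
  p_off <- allele_frequencies(fam$geno$codes[off, , drop = FALSE])
  # binomial check against the founder draw: |diff| < 3 SD of the mean of
  # 2 * n_off sampled alleles around the realised parent frequency
  par <- fam$ped$animal[is.na(fam$ped$sire)]
  p_par <- allele_frequencies(fam$geno$codes[par, , drop = FALSE])
  n_all <- 2 * length(off)
  sd3 <- 3 * sqrt(p_par * (1 - p_par) / n_all) + 3 *
    sqrt(p_par * (1 - p_par) / (2 * length(par)))
  expect_true(all(abs(p_off - p_par) < pmax(sd3, 0.05)))
})

test_that("zero-noise, no-QTL phenotypes lie exactly on the population curve", {
  cfg <- small_cfg(polygenic_cov = diag(0, 3), param_env_cov = diag(0, 3),
                   residual_sd = 0)
  fam <- simulate_families(cfg, 84)
  sim <- simulate_growth_phenotypes(fam$ped, fam$geno, cfg, 85)
  expected <- predict_weight("brody", c(A = 500, b = 0.9, K = 0.07),
                             cfg$time_points)
  for (w in sim$phenos[c(1, 50, 100)])
    expect_equal(w$weights, expected, tolerance = 1e-10)
})

test_that("a planted additive QTL moves dosage-class means by 2a", {
  cfg <- small_cfg(n_families = 150, offspring_per_family = 8,
                   polygenic_cov = diag(c(25, 1e-5, 1e-6)),
                   param_env_cov = diag(0, 3), residual_sd = 0)
  fam <- simulate_families(cfg, 86)
  qtl <- data.frame(param = "A", snp_id = fam$geno$map$snp_id[5],
                    effect = 10, size_class = "large",
                    stringsAsFactors = FALSE)
  cfg$qtl_spec <- qtl
  sim <- simulate_growth_phenotypes(fam$ped, fam$geno, cfg, 87)
  tru <- sim$truth$params
  dos <- fam$geno$codes[tru$animal, qtl$snp_id]
  m0 <- mean(tru$A[dos == 0]); m2 <- mean(tru$A[dos == 2])
  expect_lt(abs((m2 - m0) - 20), 2.5)   # approx 2 x 10 kg over a large sample
})

test_that("per-animal refits on zero-noise data return the planted parameters", {
  cfg <- small_cfg(n_families = 10, residual_sd = 0)
  fam <- simulate_families(cfg, 88)
  sim <- simulate_growth_phenotypes(fam$ped, fam$geno, cfg, 89)
  tru <- sim$truth$params; rownames(tru) <- tru$animal
  for (w in sim$phenos[seq(1, 80, by = 13)]) {
    f <- fit_animal(w, "brody")
    expect_true(f$converged)
    expect_lt(max(abs(f$params[c("A", "b", "K")] -
                        unlist(tru[w$animal_id, c("A", "b", "K")]))), 1e-6)
  }
})

test_that("within-timepoint permutation keeps marginals, kills dependence", {
  cfg <- small_cfg(n_families = 250, offspring_per_family = 8,
                   polygenic_cov = diag(c(2500, 1e-4, 4e-4)),
                   residual_sd = 2)
  fam <- simulate_families(cfg, 90)
  sim <- simulate_growth_phenotypes(fam$ped, fam$geno, cfg, 91)
  perm <- permute_within_timepoint(sim$phenos, 92)
  w0 <- weights_matrix(sim$phenos); w1 <- weights_matrix(perm)
  # multiset at each time point preserved exactly
  for (j in seq_len(ncol(w0)))
    expect_equal(sort(unname(w0[, j])), sort(unname(w1[, j])))
  # factors stay with the animal
  expect_identical(perm[[7]]$factors, sim$phenos[[7]]$factors)
  # same seed -> same permutation
  expect_equal(weights_matrix(permute_within_timepoint(sim$phenos, 92)), w1)
  # cross-timepoint correlation destroyed (2000 animals)
  r_before <- cor(w0[, 1], w0[, ncol(w0)])
  r_after <- cor(w1[, 1], w1[, ncol(w1)])
  expect_gt(abs(r_before), 0.1)
  expect_lt(abs(r_after), 0.07)
  # ragged series are rejected
  broken <- sim$phenos
  broken[[1]]$ages <- broken[[1]]$ages + 1
  expect_error(permute_within_timepoint(broken, 93), "ragged|identical")
})

test_that("polygenic covariance must be PSD", {
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(small_cfg(polygenic_cov = bad), "positive semidefinite")
})
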