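# simulate n unphased genotype pairs from given haplotype frequencies
sim_pair <- function(n, f, seed) {
  # f = (AB, Ab, aB, ab) haplotype frequencies
  set.seed(seed)
  h1 <- sample(1:4, n, TRUE, prob = f)
  h2 <- sample(1:4, n, TRUE, prob = f)
  a_of <- c(1, 1, 0, 0); b_of <- c(1, 0, 1, 0)
  cbind(a = a_of[h1] + a_of[h2], b = b_of[h1] + b_of[h2])
}

test_that("identical SNP columns are in perfect LD", {
  set.seed(801)
  g <- rbinom(200, 2, 0.4)
  codes <- cbind(s1 = g, s2 = g)
  storage.mode(codes) <- "integer"
  ld <- pairwise_ld(geno_fixture(codes), "s1", "s2")
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_false(ld$flagged)
})

test_that("independent loci show near-zero r2 on average", {
  set.seed(802)
  r2 <- replicate(60, {
    codes <- cbind(s1 = rbinom(2000, 2, runif(1, 0.2, 0.8)),
                   s2 = rbinom(2000, 2, runif(1, 0.2, 0.8)))
    storage.mode(codes) <- "integer"
    pairwise_ld(geno_fixture(codes), "s1", "s2")$r2
  })
  expect_lt(mean(r2), 0.01)
})

test_that("EM haplotype frequencies match phased truth and a grid maximiser", {
  f <- c(0.5, 0.2, 0.1, 0.2)
  gg <- sim_pair(2000, f, seed = 803)
  codes <- cbind(s1 = gg[, "a"], s2 = gg[, "b"])
  storage.mode(codes) <- "integer"
  ld <- pairwise_ld(geno_fixture(codes), "s1", "s2")
  pa <- mean(gg[, "a"]) / 2; pb <- mean(gg[, "b"]) / 2
  # true D for the generating frequencies
  expect_lt(abs(ld$D - (f[1] - (f[1] + f[2]) * (f[1] + f[3]))), 0.02)
  # grid-search oracle over D (the one free parameter given allele
  # frequencies): the EM solution must attain at least the grid's likelihood
  tab <- table(factor(gg[, "a"], levels = 0:2), factor(gg[, "b"], levels = 0:2))
  loglik_at <- function(D) {
    fr <- c(pa * pb + D, pa * (1 - pb) - D, (1 - pa) * pb - D,
            (1 - pa) * (1 - pb) + D)
    if (any(fr < 0)) return(-Inf)
    P <- matrix(0, 3, 3)
    P[1, 1] <- fr[4]^2; P[1, 2] <- 2 * fr[4] * fr[3]; P[1, 3] <- fr[3]^2
    P[2, 1] <- 2 * fr[4] * fr[2]
    P[2, 2] <- 2 * (fr[1] * fr[4] + fr[2] * fr[3])
    P[2, 3] <- 2 * fr[1] * fr[3]
    P[3, 1] <- fr[2]^2; P[3, 2] <- 2 * fr[1] * fr[2]; P[3, 3] <- fr[1]^2
    sum(tab * log(pmax(P, 1e-300)))
  }
  grid <- seq(-0.25, 0.25, by = 1e-4)
  best <- grid[which.max(vapply(grid, loglik_at, numeric(1)))]
  expect_lt(abs(ld$D - best), 1e-4)
})

test_that("D-prime and r2 are invariant to allele-label swaps", {
  f <- c(0.4, 0.3, 0.1, 0.2)
  gg <- sim_pair(500, f, seed = 804)
  codes <- cbind(s1 = gg[, "a"], s2 = gg[, "b"])
  storage.mode(codes) <- "integer"
  ld0 <- pairwise_ld(geno_fixture(codes), "s1", "s2")
  swapped <- cbind(s1 = 2L - gg[, "a"], s2 = gg[, "b"])
  storage.mode(swapped) <- "integer"
  ld1 <- pairwise_ld(geno_fixture(swapped), "s1", "s2")
  expect_equal(ld1$d_prime, ld0$d_prime, tolerance = 1e-6)
  expect_equal(ld1$r2, ld0$r2, tolerance = 1e-6)
  expect_equal(ld1$ci_low, ld0$ci_low, tolerance = 0.02)
})

test_that("a perfect-LD cluster flanked by independent SNPs forms one block", {
  set.seed(805)
  n <- 400
  core <- rbinom(n, 2, 0.5)
  codes <- cbind(x1 = rbinom(n, 2, 0.5),
                 b1 = core, b2 = core, b3 = core, b4 = core, b5 = core,
                 x2 = rbinom(n, 2, 0.5))
  storage.mode(codes) <- "integer"
  g <- geno_fixture(codes, bp = c(1e5, 2e5, 2.2e5, 2.4e5, 2.6e5, 2.8e5, 4e5))
  blocks <- gabriel_blocks(g)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$n_snps, 5L)
  expect_equal(blocks$start_bp, 2e5)
  expect_equal(blocks$end_bp, 2.8e5)
  expect_identical(strsplit(blocks$snp_ids, ",")[[1]],
                   c("b1", "b2", "b3", "b4", "b5"))
})

test_that("independent SNPs yield no blocks; two clusters give two blocks", {
  set.seed(806)
  n <- 400
  indep <- replicate(6, rbinom(n, 2, 0.5))
  storage.mode(indep) <- "integer"
  expect_equal(nrow(gabriel_blocks(geno_fixture(indep))), 0L)
  c1 <- rbinom(n, 2, 0.5); c2 <- rbinom(n, 2, 0.4)
  codes <- cbind(a1 = c1, a2 = c1, a3 = c1,
                 mid = rbinom(n, 2, 0.5),
                 z1 = c2, z2 = c2)
  storage.mode(codes) <- "integer"
  g <- geno_fixture(codes, bp = c(1e5, 1.2e5, 1.4e5, 2.5e5, 3.5e5, 3.7e5))
  blocks <- gabriel_blocks(g)
  expect_equal(nrow(blocks), 2L)
  expect_identical(strsplit(blocks$snp_ids[1], ",")[[1]], c("a1", "a2", "a3"))
  expect_identical(strsplit(blocks$snp_ids[2], ",")[[1]], c("z1", "z2"))
  # blocks never span chromosomes even in perfect LD
  g2 <- geno_fixture(cbind(a = c1, b = c1),
                     chrom = c("chr1", "chr2"), bp = c(1e5, 1e5))
  expect_equal(nrow(gabriel_blocks(g2)), 0L)
})

test_that("block variance sums member shares and respects the 100 ceiling", {
  res <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                    chrom = "chr1", bp = 1:4,
                    V_A = c(1.0, 0.8, 0.57, 97.63),
                    stringsAsFactors = FALSE)
  attr(res, "traits") <- "A"
  blocks <- data.frame(chrom = "chr1", start_bp = 1, end_bp = 3, n_snps = 3,
                       snp_ids = "s1,s2,s3", stringsAsFactors = FALSE)
  bv <- block_variance(blocks, res)
  expect_equal(bv$V_A, 2.37)
  expect_lte(bv$V_A, 100)
  expect_equal(unname(attr(bv, "genome_totals")["A"]), 100)
  single <- data.frame(chrom = "chr1", start_bp = 2, end_bp = 2, n_snps = 1,
                       snp_ids = "s2", stringsAsFactors = FALSE)
  expect_equal(block_variance(single, res)$V_A, 0.8)
  missing <- data.frame(chrom = "chr1", start_bp = 1, end_bp = 9, n_snps = 2,
                        snp_ids = "s1,s9", stringsAsFactors = FALSE)
  expect_error(block_variance(missing, res), "s9")
})
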