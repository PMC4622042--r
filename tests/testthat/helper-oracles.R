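# Independent oracles and small fixture builders shared across tests.

# recursive kinship coefficients (memoised); A = 2*phi, independent of the
# tabular construction used by the package
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  phi <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + kin(si[i], di[i]))
    } else if (i > j) {
      0.5 * (kin(si[i], j) + kin(di[i], j))
    } else {
      0.5 * (kin(si[j], i) + kin(di[j], i))
    }
    phi[i, j] <<- v; phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) kin(i, j)
  dimnames(phi) <- list(ped$animal, ped$animal)
  2 * phi
}

# random multi-generation pedigree for property tests
random_pedigree <- function(n_founders, n_children, seed) {
  set.seed(seed)
  animal <- sprintf("f%02d", seq_len(n_founders))
  sire <- dam <- rep(NA_character_, n_founders)
  for (k in seq_len(n_children)) {
    pair <- sample(animal, 2L)
    animal <- c(animal, sprintf("c%02d", k))
    sire <- c(sire, pair[1L]); dam <- c(dam, pair[2L])
  }
  pedigree_table(animal, sire, dam)
}

# full-enumeration exact HWE oracle over all het counts compatible with the
# observed allele counts, using the closed-form conditional probability
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) return(1)
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  if (nA == 0 || nB == 0) return(1)
  nr <- min(nA, nB)
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    h1 <- (nr - h) / 2
    h2 <- n - h - h1
    h * log(2) + lfactorial(n) - lfactorial(h1) - lfactorial(h) -
      lfactorial(h2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp - max(logp)); prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

# dense brute-force multivariate GLS for one SNP (trait-major stacking)
dense_gls_oracle <- function(y, w, Asub, sigma_u, sigma_e) {
  n <- nrow(y); q <- ncol(y)
  V <- kronecker(sigma_u, Asub) + kronecker(sigma_e, diag(n))
  X <- cbind(kronecker(diag(q), rep(1, n)), kronecker(diag(q), w))
  Vi <- solve(V)
  C <- solve(t(X) %*% Vi %*% X)
  est <- C %*% t(X) %*% Vi %*% as.vector(y)
  list(s = est[(q + 1):(2 * q)],
       se = sqrt(diag(C)[(q + 1):(2 * q)]))
}

# noiseless series from a model, as a weight_series
series_from_model <- function(model, params, ages = c(0, 6, 12, 15, 18, 24),
                              id = "a1", noise_sd = 0) {
  w <- predict_weight(model, params, ages)
  if (noise_sd > 0) w <- w + rnorm(length(ages), 0, noise_sd)
  weight_series(id, ages, w)
}

# tiny genotype matrix from a codes matrix with a 1-chromosome map
geno_fixture <- function(codes, chrom = NULL, bp = NULL) {
  m <- ncol(codes)
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("s%02d", 1:m)
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("a%03d", seq_len(nrow(codes)))
  map <- data.frame(snp_id = colnames(codes),
                    chrom = chrom %||% rep("chr1", m),
                    bp = bp %||% seq(1e5, by = 1e5, length.out = m),
                    stringsAsFactors = FALSE)
  genotype_matrix(codes, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
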