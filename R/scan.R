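#' Multi-trait single-SNP mixed-model association scan
#'
#' Fits, for each SNP in turn, the three-trait model
#' `Y = W s + Z u + e` with the polygenic covariance `sigma_u (x) A` and
#' residual `sigma_e (x) I` fixed at their null-model REML estimates
#' (two-stage scan: the variance components are estimated once without any
#' SNP and held fixed, the standard approximation for dense scans). The
#' system is rotated once through the eigendecomposition of the phenotyped
#' relationship matrix, after which each SNP costs one 2q x 2q generalized
#' least-squares solve. Missing genotypes are mean-imputed per SNP inside
#' the scan only; a SNP constant after imputation is returned flagged
#' untestable with `NA` results.
#'
#' Per-trait tests are Wald tests of `s_j = 0` against the normal
#' reference; the joint test is the q-degree-of-freedom chi-square on the
#' whole effect vector. Per-trait q-values come from [bh_fdr()] and the
#' per-trait variance shares from [variance_explained()] with allele
#' frequencies estimated across the scanned population.
#'
#' @param y Numeric matrix animals x traits (rownames = animal ids).
#' @param geno A `genotype_matrix` covering the animals in `y`.
#' @param vc A `variance_components` object from [reml_null()].
#' @param rel Relationship matrix covering the animals in `y`.
#' @param alpha FDR level for the significance flags (default 0.05).
#' @param p_threshold Secondary raw-p cutoff (default 0.001).
#' @return data.frame with one row per SNP: `snp_id, chrom, bp, freq`,
#'   effects `s_<trait>`, standard errors `se_<trait>`, Wald `p_<trait>`,
#'   `p_joint`, q-values `q_<trait>`, significance flags `sig_<trait>`,
#'   `below_p_<trait>`, variance shares `V_<trait>` and `untestable`.
#' @export
snp_scan <- function(y, geno, vc, rel, alpha = 0.05, p_threshold = 0.001) {
  y <- as.matrix(y)
  ids <- rownames(y)
  stopifnot(!is.null(ids), all(ids %in% geno$animal_ids))
  n <- nrow(y); q <- ncol(y)
  traits <- colnames(y) %||% paste0("trait", seq_len(q))

  Asub <- rel_subset(rel, ids)
  ed <- eigen(sympart(Asub), symmetric = TRUE)
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  ystar <- crossprod(U, y)
  cvec <- drop(crossprod(U, rep(1, n)))

  V <- outer(d, vc$sigma_u)
  for (j in seq_len(q)) for (k in seq_len(q))
    V[, j, k] <- V[, j, k] + vc$sigma_e[j, k]
  Vinv <- stack_inv(V)$inv
  ty <- stack_matvec(Vinv, ystar)                  # V^-1 y*, n x q
  A11 <- stack_wsum(Vinv, cvec^2)                  # intercept block
  b1 <- drop(crossprod(ty, cvec))

  W <- geno$codes[ids, , drop = FALSE]
  m <- ncol(W)
  freq <- suppressWarnings(allele_frequencies(W))
  # mean imputation for the scan only
  Wimp <- apply(W, 2L, function(g) {
    mu <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- mu
    g
  })
  untestable <- apply(Wimp, 2L, function(g) !is.finite(g[1L]) ||
                        stats::var(g) < 1e-12)
  Wstar <- crossprod(U, Wimp)                      # rotated dosages

  # per-SNP cross-products, accumulated trait-pair by trait-pair
  A12 <- array(0, c(q, q, m)); A22 <- array(0, c(q, q, m))
  Wsq <- Wstar^2
  for (j in seq_len(q)) for (k in seq_len(q)) {
    A12[j, k, ] <- crossprod(Wstar, cvec * Vinv[, j, k])
    A22[j, k, ] <- crossprod(Wsq, Vinv[, j, k])
  }
  b2 <- crossprod(Wstar, ty)                       # m x q

  s_hat <- se <- p_trait <- matrix(NA_real_, m, q)
  p_joint <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (untestable[i]) next
    M <- rbind(cbind(A11, A12[, , i]), cbind(t(A12[, , i]), A22[, , i]))
    rhs <- c(b1, b2[i, ])
    est <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(est)) { untestable[i] <- TRUE; next }
    Cov <- solve(M)
    s <- est[(q + 1L):(2L * q)]
    Cs <- Cov[(q + 1L):(2L * q), (q + 1L):(2L * q), drop = FALSE]
    s_hat[i, ] <- s
    se[i, ] <- sqrt(pmax(diag(Cs), 0))
    z <- s / se[i, ]
    p_trait[i, ] <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
    chi <- tryCatch(drop(t(s) %*% solve(Cs, s)), error = function(e) NA_real_)
    p_joint[i] <- pmax(stats::pchisq(chi, df = q, lower.tail = FALSE), 1e-300)
  }

  out <- data.frame(snp_id = geno$map$snp_id, chrom = geno$map$chrom,
                    bp = geno$map$bp, freq = unname(freq),
                    stringsAsFactors = FALSE)
  for (j in seq_len(q)) out[[paste0("s_", traits[j])]] <- s_hat[, j]
  for (j in seq_len(q)) out[[paste0("se_", traits[j])]] <- se[, j]
  for (j in seq_len(q)) out[[paste0("p_", traits[j])]] <- p_trait[, j]
  out$p_joint <- p_joint
  for (j in seq_len(q)) {
    ok <- !is.na(p_trait[, j])
    fdr <- bh_fdr(p_trait[ok, j], alpha = alpha, p_threshold = p_threshold)
    qv <- sg <- bp_ <- rep(NA, m)
    qv[ok] <- fdr$q; sg[ok] <- fdr$significant
    bp_[ok] <- fdr$below_p_threshold
    out[[paste0("q_", traits[j])]] <- as.numeric(qv)
    out[[paste0("sig_", traits[j])]] <- as.logical(sg)
    out[[paste0("below_p_", traits[j])]] <- as.logical(bp_)
  }
  for (j in seq_len(q)) {
    eff <- s_hat[, j]; eff[is.na(eff)] <- 0
    out[[paste0("V_", traits[j])]] <- variance_explained(eff, unname(freq))
  }
  out$untestable <- untestable
  attr(out, "traits") <- traits
  out
}
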