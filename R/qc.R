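#' Allele frequency of the counted (code-2) allele per SNP
#'
#' `p = (2 n2 + n1) / (2 n_called)` over non-missing genotypes. A SNP with
#' no called genotypes gets `NA` and is flagged via the `"undefined"`
#' attribute.
#'
#' @param geno A `genotype_matrix` or a codes matrix in {0,1,2,NA}.
#' @return Named numeric vector of frequencies in [0,1].
#' @export
allele_frequencies <- function(geno) {
  codes <- if (inherits(geno, "genotype_matrix")) geno$codes else geno
  called <- colSums(!is.na(codes))
  p <- colSums(codes, na.rm = TRUE) / (2 * called)
  p[called == 0L] <- NA_real_
  if (any(called == 0L)) {
    attr(p, "undefined") <- colnames(codes)[called == 0L]
    warning("SNP(s) with no called genotypes: frequency undefined")
  }
  p
}

#' Exact two-sided Hardy-Weinberg test
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count (the standard exact HWE test). Computed with a
#' log-space recurrence over compatible heterozygote counts, so it is
#' stable for large samples.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (first-allele homozygotes,
#'   heterozygotes, second-allele homozygotes).
#' @return Two-sided exact p-value in (0,1]; `p = 1` for an empty or
#'   monomorphic sample (no polymorphism to test).
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_a <- 2L * n_hom1 + n_het          # rare-or-not allele 1 count
  n_b <- 2L * n_hom2 + n_het
  if (n_a == 0L || n_b == 0L) return(1)
  n_rare <- min(n_a, n_b)
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)  # compatible het counts
  # log P(het) up to a constant, via the ratio
  # P(h+2)/P(h) = 4 * n1(h) * n2(h) / ((h+2)(h+1))
  # where n1(h) = (n_rare - h)/2, n2(h) = (n - n_rare/2 - h/2 - ...)
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1L]) {
    h <- hets[i - 1L]
    hom_r <- (n_rare - h) / 2        # rare-allele homozygotes at het = h
    hom_c <- n - h - hom_r           # common-allele homozygotes
    logp[i] <- logp[i - 1L] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  p_obs <- prob[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Applies, in order: individual call rate, SNP call rate, minor allele
#' frequency, and the exact Hardy-Weinberg test. Individuals or SNPs with a
#' call rate strictly below the threshold, SNPs with MAF strictly below the
#' MAF threshold, and SNPs with HWE p strictly below `hwe_p` are removed.
#' Missingness is preserved (no imputation here).
#'
#' @param geno A `genotype_matrix`.
#' @param thresholds List with `ind_call` (default 0.95), `snp_call`
#'   (default 0.95), `maf` (default 0.01) and `hwe_p` (default 1e-7).
#' @return List with the filtered `genotype_matrix` and a `report`
#'   data.frame counting removals at each step.
#' @export
qc_filter <- function(geno, thresholds = list()) {
  th <- utils::modifyList(
    list(ind_call = 0.95, snp_call = 0.95, maf = 0.01, hwe_p = 1e-7),
    thresholds)
  stopifnot(all(unlist(th[c("ind_call", "snp_call", "maf")]) >= 0),
            all(unlist(th[c("ind_call", "snp_call", "maf")]) <= 1))
  codes <- geno$codes
  report <- data.frame(step = character(0), removed = integer(0),
                       kept = integer(0), stringsAsFactors = FALSE)
  note <- function(step, removed, kept)
    rbind(report, data.frame(step = step, removed = removed, kept = kept,
                             stringsAsFactors = FALSE))

  ind_cr <- rowMeans(!is.na(codes))
  keep_i <- ind_cr >= th$ind_call
  report <- note("individual_call_rate", sum(!keep_i), sum(keep_i))
  codes <- codes[keep_i, , drop = FALSE]

  snp_cr <- colMeans(!is.na(codes))
  keep_s <- snp_cr >= th$snp_call
  report <- note("snp_call_rate", sum(!keep_s), sum(keep_s))
  codes <- codes[, keep_s, drop = FALSE]

  p <- suppressWarnings(allele_frequencies(codes))
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf >= th$maf
  report <- note("maf", sum(!keep_m), sum(keep_m))
  codes <- codes[, keep_m, drop = FALSE]

  hwe_p <- apply(codes, 2L, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  keep_h <- hwe_p >= th$hwe_p
  report <- note("hwe", sum(!keep_h), sum(keep_h))
  codes <- codes[, keep_h, drop = FALSE]

  if (ncol(codes) == 0L) {
    err <- simpleError("all SNPs removed by QC")
    err$report <- report
    stop(err)
  }
  keep_ids <- colnames(codes)
  out <- genotype_matrix(codes,
                         geno$map[match(keep_ids, geno$map$snp_id), ,
                                  drop = FALSE],
                         geno$alleles[match(keep_ids, geno$map$snp_id)])
  list(geno = out, report = report)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values (monotone by construction) with a primary significance
#' call `q < alpha` and, as a separate flag, the raw-p rule `p <
#' p_threshold` that some studies layer on top. The two rules are reported
#' side by side, never silently combined.
#'
#' @param pvalues Numeric vector of p-values in (0,1].
#' @param alpha FDR level (default 0.05).
#' @param p_threshold Secondary raw-p cutoff (default 0.001).
#' @return data.frame with `p`, `q`, `significant` (q < alpha) and
#'   `below_p_threshold`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05, p_threshold = 0.001) {
  if (length(pvalues) == 0L)
    return(data.frame(p = numeric(0), q = numeric(0),
                      significant = logical(0),
                      below_p_threshold = logical(0)))
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, significant = q < alpha,
             below_p_threshold = pvalues < p_threshold)
}

#' Percentage of marker-attributed genetic variance per SNP
#'
#' `V_i = 100 * 2 p_i q_i s_i^2 / sum_j 2 p_j q_j s_j^2`, the share of the
#' variance attributed to markers that SNP i carries for one trait; the
#' denominator runs over all scanned SNPs of that trait. A monomorphic SNP
#' (2pq = 0) gets `V_i = 0` regardless of its estimated effect; if every
#' term is zero the whole vector is zero with a warning.
#'
#' @param effects Numeric vector (one trait) or matrix (SNPs x traits) of
#'   estimated additive effects.
#' @param freqs Per-SNP allele frequencies aligned with `effects`.
#' @return Same shape as `effects`, percentages summing to 100 per trait
#'   (when any effect is nonzero).
#' @export
variance_explained <- function(effects, freqs) {
  if (is.matrix(effects)) {
    out <- apply(effects, 2L, variance_explained, freqs = freqs)
    dimnames(out) <- dimnames(effects)
    return(out)
  }
  stopifnot(length(effects) == length(freqs))
  w <- 2 * freqs * (1 - freqs) * effects^2
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    warning("all 2pq*s^2 terms are zero; V_i set to 0")
    return(rep(0, length(w)))
  }
  100 * w / tot
}
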