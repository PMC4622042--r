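# Two-locus linkage disequilibrium from unphased genotypes, and
# Gabriel-style haplotype blocks built from D' confidence intervals.

# EM for two-locus haplotype frequencies from a 3 x 3 genotype count table
# (rows = locus a dosage 0/1/2, cols = locus b dosage). Only the double
# heterozygote is phase-ambiguous; its mass is split by the current phase
# probabilities each iteration.
haplotype_em <- function(tab, tol = 1e-10, max_iter = 1000L) {
  n <- sum(tab)
  # known haplotype counts contributed by unambiguous genotypes
  # haplotypes: 11 (AB), 12 (Ab), 21 (aB), 22 (ab) w.r.t. allele coded 1
  base <- c(`11` = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
            `12` = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
            `21` = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            `22` = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  dh <- tab[2, 2]
  f <- rep(0.25, 4)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    pcis <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base + dh * c(pcis, 1 - pcis, 1 - pcis, pcis)
    f_new <- cnt / (2 * n)
    if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  list(freq = f, converged = converged)
}

# log-likelihood of the 9 genotype classes given haplotype frequencies
geno_loglik <- function(tab, f) {
  # P(genotype at both loci) assuming random union of haplotypes
  pAB <- f[1]; pAb <- f[2]; paB <- f[3]; pab <- f[4]
  P <- matrix(0, 3, 3)
  P[1, 1] <- pab^2;            P[1, 2] <- 2 * pab * paB; P[1, 3] <- paB^2
  P[2, 1] <- 2 * pab * pAb
  P[2, 2] <- 2 * (pAB * pab + pAb * paB)
  P[2, 3] <- 2 * pAB * paB
  P[3, 1] <- pAb^2;            P[3, 2] <- 2 * pAB * pAb; P[3, 3] <- pAB^2
  sum(tab * log(pmax(P, 1e-300)))
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Haplotype frequencies are estimated by the two-locus EM over unphased
#' genotypes; D, D' and r-squared follow from the converged frequencies.
#' The 90% confidence interval on D' is the likelihood-profile interval:
#' holding the allele frequencies at their estimates and fixing the sign
#' of D, the genotype likelihood is evaluated over a grid of |D'| values,
#' normalised, and the 5th and 95th percentiles of the resulting
#' distribution are returned (the construction used for Gabriel-style
#' block calling).
#'
#' @param geno A `genotype_matrix` or codes matrix.
#' @param snp_a,snp_b SNP ids (or column indices).
#' @param min_n Minimum animals called on both SNPs (default 20).
#' @return An `ld_estimate`: `snp_a, snp_b, n, D, d_prime, r2, ci_low,
#'   ci_high, converged, flagged` (TRUE when the estimate is degenerate,
#'   e.g. a monomorphic locus).
#' @export
pairwise_ld <- function(geno, snp_a, snp_b, min_n = 20L) {
  codes <- if (inherits(geno, "genotype_matrix")) geno$codes else geno
  ga <- codes[, snp_a]; gb <- codes[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  out <- list(snp_a = if (is.character(snp_a)) snp_a else colnames(codes)[snp_a],
              snp_b = if (is.character(snp_b)) snp_b else colnames(codes)[snp_b],
              n = n, D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              converged = FALSE, flagged = TRUE)
  class(out) <- "ld_estimate"
  if (n < min_n) return(out)
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(out)  # monomorphic

  tab <- table(factor(ga, levels = 0:2), factor(gb, levels = 0:2))
  em <- haplotype_em(tab)
  f <- unname(em$freq)
  D <- f[1] - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) return(out)
  out$D <- D
  out$d_prime <- min(abs(D) / dmax, 1)
  out$r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  out$converged <- em$converged
  # profile CI over |D'|
  grid <- seq(0, 1, length.out = 201L)
  ll <- vapply(grid, function(dp) {
    Dg <- sign(D) * dp * dmax
    fg <- c(pa * pb + Dg, pa * (1 - pb) - Dg,
            (1 - pa) * pb - Dg, (1 - pa) * (1 - pb) + Dg)
    # fg ordered as (AB, Ab, aB, ab) with A,B the allele coded 1
    fg <- pmax(fg, 0)
    geno_loglik(tab, c(fg[1], fg[2], fg[3], fg[4]))
  }, numeric(1L))
  lk <- exp(ll - max(ll))
  cdf <- cumsum(lk) / sum(lk)
  out$ci_low <- grid[which(cdf >= 0.05)[1L]]
  out$ci_high <- grid[which(cdf >= 0.95)[1L]]
  out$flagged <- !em$converged
  out
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("<ld_estimate> %s ~ %s: D'=%.3f [%.2f, %.2f], r2=%.3f (n=%d)\n",
              x$snp_a, x$snp_b, x$d_prime, x$ci_low, x$ci_high, x$r2, x$n))
  invisible(x)
}

#' Gabriel-style haplotype blocks from D' confidence intervals
#'
#' A SNP pair is in "strong LD" when the 90% D' CI has lower bound at least
#' `ci_low` and upper bound at least `ci_high`; it shows "strong evidence
#' of recombination" when the upper bound is below `recomb_high`. A
#' candidate interval of map-consecutive SNPs is a block when at least
#' `strong_frac` of its informative pairs (pairs that are either strong LD
#' or strong recombination) are strong LD. Maximal non-overlapping blocks
#' are chosen greedily by bp span, ties to the leftmost. Blocks never
#' cross chromosomes and are bounded by `max_span_bp`.
#'
#' @param geno A `genotype_matrix` (map-sorted within chromosome).
#' @param snp_ids Optional subset of SNPs to consider (e.g. the significant
#'   set); default all.
#' @param ci_low,ci_high Strong-LD thresholds on the D' CI (0.70, 0.98).
#' @param recomb_high Strong-recombination threshold on the CI upper bound
#'   (0.90).
#' @param strong_frac Required fraction of informative pairs in strong LD
#'   (0.95).
#' @param max_span_bp Maximum block span in bp (default 500 kb).
#' @param min_n Minimum paired calls per LD estimate.
#' @return data.frame of blocks: `chrom, start_bp, end_bp, n_snps, snp_ids`
#'   (comma-joined, map order).
#' @export
gabriel_blocks <- function(geno, snp_ids = NULL, ci_low = 0.70,
                           ci_high = 0.98, recomb_high = 0.90,
                           strong_frac = 0.95, max_span_bp = 5e5,
                           min_n = 20L) {
  map <- geno$map
  if (!is.null(snp_ids)) map <- map[map$snp_id %in% snp_ids, , drop = FALSE]
  blocks <- list()
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$bp), , drop = FALSE]
    k <- nrow(sub)
    if (k < 2L) next
    # pair status: 1 strong LD, -1 strong recombination, 0 uninformative
    status <- matrix(0L, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (sub$bp[j] - sub$bp[i] > max_span_bp) break
      ld <- pairwise_ld(geno, sub$snp_id[i], sub$snp_id[j], min_n = min_n)
      if (is.na(ld$ci_low)) next
      if (ld$ci_low >= ci_low && ld$ci_high >= ci_high) status[i, j] <- 1L
      else if (ld$ci_high < recomb_high) status[i, j] <- -1L
    }
    cand <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (sub$bp[j] - sub$bp[i] > max_span_bp) break
      st <- status[i:j, i:j]
      inform <- sum(st != 0L)
      if (inform == 0L) next
      if (sum(st == 1L) / inform >= strong_frac)
        cand[[length(cand) + 1L]] <-
          list(i = i, j = j, span = sub$bp[j] - sub$bp[i])
    }
    if (length(cand) == 0L) next
    spans <- vapply(cand, function(x) x$span, numeric(1L))
    lefts <- vapply(cand, function(x) x$i, integer(1L))
    ord <- order(-spans, lefts)
    used <- rep(FALSE, k)
    for (ci in ord) {
      rng <- cand[[ci]]$i:cand[[ci]]$j
      if (any(used[rng])) next
      used[rng] <- TRUE
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = ch, start_bp = sub$bp[cand[[ci]]$i],
        end_bp = sub$bp[cand[[ci]]$j], n_snps = length(rng),
        snp_ids = paste(sub$snp_id[rng], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(blocks) == 0L)
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      snp_ids = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-SNP variance shares over haplotype blocks
#'
#' Sums each block's member `V_<trait>` columns from a [snp_scan()] result
#' table; also attaches the genome-wide totals per trait as an attribute.
#'
#' @param blocks Block table from [gabriel_blocks()].
#' @param snp_results A [snp_scan()] result covering every member SNP.
#' @return `blocks` with one `V_<trait>` column per trait filled in;
#'   attribute `"genome_totals"` holds the per-trait totals over all
#'   scanned SNPs.
#' @export
block_variance <- function(blocks, snp_results) {
  traits <- attr(snp_results, "traits") %||%
    sub("^V_", "", grep("^V_", names(snp_results), value = TRUE))
  for (tr in traits) {
    col <- paste0("V_", tr)
    blocks[[col]] <- vapply(seq_len(nrow(blocks)), function(i) {
      members <- strsplit(blocks$snp_ids[i], ",")[[1L]]
      idx <- match(members, snp_results$snp_id)
      if (anyNA(idx))
        stop("block member SNP missing from scan results: ",
             members[which(is.na(idx))[1L]])
      sum(snp_results[[col]][idx])
    }, numeric(1L))
  }
  attr(blocks, "genome_totals") <- vapply(
    traits, function(tr) sum(snp_results[[paste0("V_", tr)]], na.rm = TRUE),
    numeric(1L))
  blocks
}
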