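#' Nearest-gene annotation for significant SNPs
#'
#' For each SNP, reports every gene on the same chromosome within
#' `max_dist` bp, sorted by absolute distance (ties broken by gene id). A
#' SNP inside a gene gets distance 0; otherwise the distance is signed,
#' positive when the gene starts downstream (higher bp) of the SNP and
#' negative when it ends upstream. A SNP with no gene in range yields no
#' rows.
#'
#' @param snps data.frame with at least `snp_id, chrom, bp` (e.g. the
#'   significant rows of a [snp_scan()] result).
#' @param genes A `gene_table` (1-based inclusive).
#' @param max_dist Maximum SNP-gene distance in bp (default 1 Mb).
#' @return data.frame `snp_id, gene_id, distance`, ordered by SNP then
#'   |distance| then gene id.
#' @export
nearest_genes <- function(snps, genes, max_dist = 1e6) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chrom == snps$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    bp <- snps$bp[i]
    dist <- ifelse(bp >= g$start & bp <= g$end, 0,
                   ifelse(bp < g$start, g$start - bp, g$end - bp))
    keep <- abs(dist) <= max_dist
    if (!any(keep)) next
    hit <- data.frame(snp_id = snps$snp_id[i], gene_id = g$gene_id[keep],
                      distance = dist[keep], stringsAsFactors = FALSE)
    hit <- hit[order(abs(hit$distance), hit$gene_id), , drop = FALSE]
    out[[length(out) + 1L]] <- hit
  }
  if (length(out) == 0L)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' QTL detection power over simulation replicates
#'
#' A planted QTL counts as detected in a replicate when at least one SNP
#' significant for the corresponding curve parameter lies within `window`
#' bp of it on the same chromosome. Power is `100 * detections /
#' replicates`, reported separately for the large-effect QTL and as the
#' mean over the small-effect QTL of each parameter.
#'
#' @param replicate_results List of [snp_scan()] result tables.
#' @param truth_qtl QTL truth table (`param, snp_id, effect, size_class,
#'   chrom, bp`), as produced by [simulate_growth_phenotypes()].
#' @param window Detection window in bp (default 5e6, i.e. 5 cM on the
#'   simulated 1 cM = 1 Mb maps).
#' @param sig_column Which per-trait flag marks significance: `"sig"`
#'   (BH q < alpha) or `"below_p"` (raw p below the threshold).
#' @return data.frame per parameter: `param, large_pct, small_pct,
#'   n_replicates`.
#' @export
detection_power <- function(replicate_results, truth_qtl, window = 5e6,
                            sig_column = c("sig", "below_p")) {
  sig_column <- match.arg(sig_column)
  if (window <= 0) stop("window must be positive")
  if (length(replicate_results) == 0L) stop("need at least one replicate")
  params <- unique(truth_qtl$param)
  rows <- lapply(params, function(pp) {
    qtl <- truth_qtl[truth_qtl$param == pp, , drop = FALSE]
    det <- matrix(FALSE, length(replicate_results), nrow(qtl))
    for (r in seq_along(replicate_results)) {
      res <- replicate_results[[r]]
      flag <- res[[paste0(sig_column, "_", pp)]]
      sig <- res[!is.na(flag) & flag, , drop = FALSE]
      if (nrow(sig) == 0L) next
      for (k in seq_len(nrow(qtl)))
        det[r, k] <- any(sig$chrom == qtl$chrom[k] &
                           abs(sig$bp - qtl$bp[k]) <= window)
    }
    large <- qtl$size_class == "large"
    data.frame(param = pp,
               large_pct = 100 * mean(det[, large, drop = FALSE]),
               small_pct = 100 * mean(det[, !large, drop = FALSE]),
               n_replicates = length(replicate_results),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render Manhattan, QQ and genotype-curve plots
#'
#' Manhattan plots show -log10(q) per trait with chromosomes alternately
#' coloured and a horizontal line at the FDR threshold; QQ plots compare
#' observed against expected -log10(p) per trait; the genotype-curve plot
#' evaluates the growth model at the within-genotype-class mean fitted
#' parameters over a fine age grid for one marker.
#'
#' @param results A [snp_scan()] result table.
#' @param out_dir Output directory (created if needed).
#' @param alpha FDR threshold drawn on the Manhattan plots.
#' @param fits Optional list of converged `growth_fit`s (needed for the
#'   genotype-curve plot).
#' @param geno Optional `genotype_matrix` (needed for the genotype-curve
#'   plot).
#' @param marker Optional SNP id for the genotype-curve plot; unknown ids
#'   are an error.
#' @param model Growth model name for the genotype curves.
#' @param ages Age grid over which to draw the genotype curves.
#' @return Character vector of written file paths, invisibly.
#' @export
render_plots <- function(results, out_dir, alpha = 0.05, fits = NULL,
                         geno = NULL, marker = NULL, model = "brody",
                         ages = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traits <- attr(results, "traits") %||%
    sub("^q_", "", grep("^q_", names(results), value = TRUE))
  written <- character(0)
  # stable x position: cumulative bp offset per chromosome
  chroms <- unique(results$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(results$bp[results$chrom == ch]), numeric(1L))))[seq_along(chroms)]
  names(offs) <- chroms
  xpos <- results$bp + offs[results$chrom]
  for (tr in traits) {
    qv <- results[[paste0("q_", tr)]]
    df <- data.frame(x = xpos, y = -log10(pmax(qv, 1e-300)),
                     chrom = factor(results$chrom, levels = chroms))
    df <- df[!is.na(qv), , drop = FALSE]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = chrom)) +
      ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
      ggplot2::scale_colour_manual(values = rep(c("grey25", "steelblue"),
                                                length.out = length(chroms))) +
      ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                          colour = "red") +
      ggplot2::labs(x = "genome position", y = "-log10(q)",
                    title = paste("Manhattan:", tr))
    f <- file.path(out_dir, paste0("manhattan_", tr, ".png"))
    ggplot2::ggsave(f, p, width = 8, height = 3, dpi = 120)
    written <- c(written, f)

    pv <- sort(results[[paste0("p_", tr)]])
    pv <- pv[!is.na(pv)]
    dfq <- data.frame(exp = -log10(stats::ppoints(length(pv))),
                      obs = -log10(pv))
    pq <- ggplot2::ggplot(dfq, ggplot2::aes(x = exp, y = obs)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
      ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)",
                    title = paste("QQ:", tr))
    f <- file.path(out_dir, paste0("qq_", tr, ".png"))
    ggplot2::ggsave(f, pq, width = 4, height = 4, dpi = 120)
    written <- c(written, f)
  }
  if (!is.null(marker)) {
    if (is.null(fits) || is.null(geno))
      stop("genotype-curve plot needs fits and geno")
    if (!marker %in% colnames(geno$codes))
      stop("unknown marker id: ", marker)
    conv <- Filter(function(f) f$converged, fits)
    ids <- vapply(conv, function(f) f$animal_id, character(1L))
    dos <- geno$codes[ids, marker]
    pm <- do.call(rbind, lapply(conv, function(f) f$params[c("A", "b", "K")]))
    if (is.null(ages))
      ages <- seq(0, max(vapply(conv, function(f) 24, numeric(1L))),
                  length.out = 100L)
    curves <- do.call(rbind, lapply(sort(unique(dos[!is.na(dos)])),
                                    function(g) {
      mp <- colMeans(pm[which(dos == g), , drop = FALSE])
      data.frame(age = ages,
                 weight = predict_weight(model, mp, ages),
                 genotype = factor(g, levels = 0:2))
    }))
    pg <- ggplot2::ggplot(curves, ggplot2::aes(x = age, y = weight, colour = genotype)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "age", y = "weight (kg)",
                    title = paste("Genotype growth curves:", marker))
    f <- file.path(out_dir, paste0("genotype_curves_", marker, ".png"))
    ggplot2::ggsave(f, pg, width = 5, height = 4, dpi = 120)
    written <- c(written, f)
  }
  invisible(written)
}

#' Within-genotype-class mean curve parameters for one marker
#'
#' The construction behind the genotype-curve figures: converged per-animal
#' fits are grouped by the marker's genotype class and the fitted
#' parameters averaged within class.
#'
#' @param fits List of `growth_fit`s.
#' @param geno A `genotype_matrix`.
#' @param marker SNP id.
#' @return data.frame `genotype, n, A, b, K`.
#' @export
genotype_class_params <- function(fits, geno, marker) {
  if (!marker %in% colnames(geno$codes))
    stop("unknown marker id: ", marker)
  conv <- Filter(function(f) f$converged, fits)
  ids <- vapply(conv, function(f) f$animal_id, character(1L))
  dos <- geno$codes[ids, marker]
  pm <- do.call(rbind, lapply(conv, function(f) f$params[c("A", "b", "K")]))
  do.call(rbind, lapply(sort(unique(dos[!is.na(dos)])), function(g) {
    sel <- which(dos == g)
    data.frame(genotype = g, n = length(sel),
               A = mean(pm[sel, "A"]), b = mean(pm[sel, "b"]),
               K = mean(pm[sel, "K"]))
  }))
}

utils::globalVariables(c("x", "y", "chrom", "obs", "age", "weight",
                         "genotype"))
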