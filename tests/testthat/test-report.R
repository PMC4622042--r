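test_that("nearest-gene annotation follows the distance and tie rules", {
  genes <- gene_table(c("G_in", "G_left", "G_right", "G_far", "G_other"),
                      c("chr1", "chr1", "chr1", "chr1", "chr2"),
                      start = c(101, 10, 650, 2e6 + 150, 100),
                      end = c(200, 40, 700, 2e6 + 250, 200))
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = c("chr1", "chr1"),
                     bp = c(150, 500), stringsAsFactors = FALSE)
  hits <- nearest_genes(snps, genes)
  h1 <- hits[hits$snp_id == "s1", ]
  expect_equal(h1$distance[h1$gene_id == "G_in"], 0)      # inside the gene
  h2 <- hits[hits$snp_id == "s2", ]
  expect_equal(h2$distance[h2$gene_id == "G_right"], 150) # downstream +
  expect_equal(h2$distance[h2$gene_id == "G_left"], -460) # upstream -
  # 1.2 Mb away: outside the 1 Mb default
  far_snp <- data.frame(snp_id = "s3", chrom = "chr1", bp = 2e6 + 150 - 1.2e6)
  expect_equal(nrow(nearest_genes(far_snp,
                                  genes[genes$gene_id == "G_far", ])), 0L)
  # equidistant genes: both reported, id order
  tie_genes <- gene_table(c("GB", "GA"), c("chr1", "chr1"),
                          start = c(1500, 100), end = c(1600, 500))
  tie_snp <- data.frame(snp_id = "t", chrom = "chr1", bp = 1000)
  th <- nearest_genes(tie_snp, tie_genes)
  expect_equal(th$gene_id, c("GA", "GB"))
  expect_equal(abs(th$distance), c(500, 500))
  # invariance to gene-table input order
  th2 <- nearest_genes(tie_snp, tie_genes[2:1, ])
  expect_equal(th, th2)
})

fake_scan <- function(sig_bp, chrom = "chr1", all_bp = seq(1e6, 9e6, by = 1e6)) {
  data.frame(snp_id = paste0("s", seq_along(all_bp)), chrom = chrom,
             bp = all_bp, sig_A = all_bp %in% sig_bp,
             below_p_A = all_bp %in% sig_bp, stringsAsFactors = FALSE)
}

test_that("detection power counts QTL hits within the window", {
  truth <- data.frame(param = "A", snp_id = "q1", effect = 1,
                      size_class = c("large", "small"),
                      chrom = "chr1", bp = c(3e6, 7e6),
                      stringsAsFactors = FALSE)
  # significant SNP exactly at each QTL in every replicate: 100%
  reps <- list(fake_scan(c(3e6, 7e6)), fake_scan(c(3e6, 7e6)))
  pw <- detection_power(reps, truth)
  expect_equal(pw$large_pct, 100)
  expect_equal(pw$small_pct, 100)
  # nothing significant: 0%
  pw0 <- detection_power(list(fake_scan(numeric(0))), truth)
  expect_equal(pw0$large_pct, 0)
  expect_equal(pw0$small_pct, 0)
  # monotone in window size: a hit 6 Mb away counts only with a wider window
  reps2 <- list(fake_scan(9e6))
  near <- detection_power(reps2, truth, window = 1e6)
  wide <- detection_power(reps2, truth, window = 2.5e6)
  expect_lte(near$small_pct, wide$small_pct)
  expect_equal(wide$small_pct, 100)   # 7 Mb QTL vs 9 Mb hit
  expect_error(detection_power(reps2, truth, window = 0), "positive")
})

test_that("plots render for normal and empty-significance inputs", {
  set.seed(901)
  m <- 40
  res <- data.frame(snp_id = paste0("s", 1:m),
                    chrom = rep(c("chr1", "chr2"), each = m / 2),
                    bp = rep(seq(1e6, by = 1e6, length.out = m / 2), 2),
                    stringsAsFactors = FALSE)
  for (tr in c("A", "b", "K")) {
    res[[paste0("p_", tr)]] <- runif(m)
    res[[paste0("q_", tr)]] <- p.adjust(res[[paste0("p_", tr)]], "BH")
  }
  attr(res, "traits") <- c("A", "b", "K")
  out <- tempfile("plots")
  files <- render_plots(res, out)
  expect_length(files, 6L)          # manhattan + qq per trait
  expect_true(all(file.exists(files)))
  # genotype-curve plot from class-mean parameters
  ages <- c(0, 6, 12, 15, 18, 24)
  fits <- lapply(1:30, function(i) {
    structure(list(animal_id = sprintf("a%03d", i), model = "brody",
                   params = c(A = 500 + rnorm(1, 0, 20), b = 0.9,
                              K = 0.06 + rnorm(1, 0, 0.004)),
                   converged = TRUE), class = "growth_fit")
  })
  codes <- matrix(rbinom(30, 2, 0.5), 30, 1,
                  dimnames = list(sprintf("a%03d", 1:30), "s1"))
  storage.mode(codes) <- "integer"
  g <- geno_fixture(codes)
  cp <- genotype_class_params(fits, g, "s1")
  expect_true(all(cp$n > 0))
  expect_equal(sum(cp$n), 30)
  # class means really are within-class means of the fitted parameters
  dos <- codes[, 1]
  expect_equal(cp$A[cp$genotype == 0],
               mean(vapply(fits[dos == 0], function(f) f$params[["A"]],
                           numeric(1))))
  f2 <- render_plots(res, out, fits = fits, geno = g, marker = "s1")
  expect_true(any(grepl("genotype_curves", f2)))
  expect_error(render_plots(res, out, fits = fits, geno = g, marker = "nope"),
               "unknown marker")
})
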