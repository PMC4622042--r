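#' Configuration for the full-sib population simulator
#'
#' Describes a population of unrelated full-sib families genotyped on
#' evenly spaced SNPs, with growth-curve parameters controlled by planted
#' QTL, a pedigree-structured polygenic term and independent parameter
#' noise, and weights generated from a chosen growth model plus i.i.d.
#' residual noise at fixed ages.
#'
#' @param n_families Number of unrelated full-sib families.
#' @param offspring_per_family Offspring per family.
#' @param n_snps Total SNPs, split as evenly as possible over chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in Morgans (all equal).
#' @param time_points Ages at which weights are recorded.
#' @param curve_model Growth model name (see [growth_model()]).
#' @param population_params Named vector of population-mean curve
#'   parameters (A, b, K and optionally M).
#' @param qtl_per_param Number of QTL per curve parameter when `qtl_spec`
#'   is auto-generated: one large (effect `large_effect_sd` genetic SDs)
#'   plus `qtl_per_param - 1` small ones (`small_effect_sd` genetic SDs).
#' @param large_effect_sd,small_effect_sd QTL allele-substitution effects
#'   in units of the target parameter's polygenic SD (defaults 1.0, 0.2).
#' @param qtl_spec Optional explicit data.frame `param, snp_id, effect`
#'   overriding the auto-generated QTL; `NULL` with `qtl_per_param = 0`
#'   plants no QTL.
#' @param polygenic_cov Genetic covariance of (A, b, K) across animals
#'   (3 x 3, symmetric PSD).
#' @param param_env_cov Independent (non-genetic) covariance added to each
#'   animal's parameters; default zero matrix.
#' @param residual_sd SD (kg) of the i.i.d. noise added to each weight.
#' @param phenotyped_per_family How many offspring per family carry
#'   phenotypes (and are scanned); default all.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_families, offspring_per_family, n_snps,
                       n_chromosomes, chromosome_length = 1,
                       time_points, curve_model = "logistic",
                       population_params,
                       qtl_per_param = 6L, large_effect_sd = 1.0,
                       small_effect_sd = 0.2, qtl_spec = NULL,
                       polygenic_cov, param_env_cov = NULL,
                       residual_sd, phenotyped_per_family = NULL) {
  stopifnot(n_families >= 1, offspring_per_family >= 1, n_snps >= 1,
            n_chromosomes >= 1, chromosome_length > 0, residual_sd >= 0)
  if (n_snps < n_chromosomes)
    stop("need at least one SNP per chromosome (n_snps < n_chromosomes)")
  polygenic_cov <- sympart(as.matrix(polygenic_cov))
  if (min(eigen(polygenic_cov, symmetric = TRUE, only.values = TRUE)$values)
      < -1e-8 * max(1, max(abs(polygenic_cov))))
    stop("polygenic_cov is not positive semidefinite")
  if (is.null(param_env_cov))
    param_env_cov <- matrix(0, nrow(polygenic_cov), ncol(polygenic_cov))
  cfg <- list(n_families = as.integer(n_families),
              offspring_per_family = as.integer(offspring_per_family),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              time_points = as.numeric(time_points),
              curve_model = curve_model,
              population_params = population_params,
              qtl_per_param = as.integer(qtl_per_param),
              large_effect_sd = large_effect_sd,
              small_effect_sd = small_effect_sd,
              qtl_spec = qtl_spec,
              polygenic_cov = polygenic_cov,
              param_env_cov = sympart(as.matrix(param_env_cov)),
              residual_sd = residual_sd,
              phenotyped_per_family =
                as.integer(phenotyped_per_family %||% offspring_per_family))
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulation configurations
#'
#' `"qtlmas2009"` mirrors the QTLMAS2009 community benchmark design:
#' 100 full-sib families of 20 offspring, half of each family phenotyped
#' and genotyped (1,000 scanned animals), 453 SNPs over 5 chromosomes of
#' 1 Morgan, logistic growth observed at days 0, 132, 265, 397 and 530,
#' and 6 QTL per curve parameter (one large, five small). Parameter-level
#' heritability is 0.3 per trait.
#'
#' `"brahman_like"` emulates the cattle cohort the pipeline targets: 251
#' full-sib families of 5 (1,255 phenotyped offspring), Brody growth at
#' 0/6/12/15/18/24 months with population means A = 520.32 kg, b = 0.92,
#' K = 0.06 per month, weight residual SD 19.57 kg, genetic parameters
#' h2 = (0.23, 0.41, 0.31) and genetic correlations (0.78, -0.84, -0.88)
#' for (A,b), (A,K), (b,K), and no planted QTL (a pure polygenic
#' architecture for variance-component work).
#'
#' @param name Preset name.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("qtlmas2009", "brahman_like")) {
  name <- match.arg(name)
  if (name == "qtlmas2009") {
    sigma_p <- c(A = 50, b = 0.9, K = 0.0012)     # total parameter SD
    h2 <- 0.3
    return(sim_config(
      n_families = 100L, offspring_per_family = 20L,
      n_snps = 453L, n_chromosomes = 5L, chromosome_length = 1,
      time_points = c(0, 132, 265, 397, 530),
      curve_model = "logistic",
      population_params = c(A = 500, b = 9, K = 0.012),
      qtl_per_param = 6L,
      polygenic_cov = diag(h2 * sigma_p^2, 3),
      param_env_cov = diag((1 - h2) * sigma_p^2, 3),
      residual_sd = 5,
      phenotyped_per_family = 10L))
  }
  # brahman_like: h2 and rg planted at the true-parameter level; the A
  # spread is chosen so per-animal least-squares fit error (~86 kg at this
  # noise level) brings the estimate SD near 164 kg. Vignette, section 3.
  rg <- matrix(c(1, 0.78, -0.84,
                 0.78, 1, -0.88,
                 -0.84, -0.88, 1), 3, 3)
  h2 <- c(A = 0.23, b = 0.41, K = 0.31)
  sigma_tot <- c(A = 139.1, b = 0.02, K = 0.012)  # true-parameter SDs
  sd_u <- sqrt(h2) * sigma_tot
  Su <- diag(sd_u) %*% rg %*% diag(sd_u)
  sd_e <- sqrt(1 - h2) * sigma_tot
  sim_config(
    n_families = 251L, offspring_per_family = 5L,
    n_snps = 50L, n_chromosomes = 5L, chromosome_length = 1,
    time_points = c(0, 6, 12, 15, 18, 24),
    curve_model = "brody",
    population_params = c(A = 520.32, b = 0.92, K = 0.06),
    qtl_per_param = 0L,
    polygenic_cov = Su,
    param_env_cov = diag(sd_e^2, 3),
    residual_sd = sqrt(382.79))
}

#' Simulate a full-sib pedigree and its genotypes
#'
#' Founder (parent) haplotypes are drawn from per-SNP allele frequencies
#' sampled once from Uniform(0.1, 0.9); SNPs sit evenly spaced along each
#' chromosome and gametes recombine with the Haldane map function (no
#' interference): the recombination fraction between adjacent markers at
#' map distance d Morgans is `(1 - exp(-2d)) / 2`. Chromosomes assort
#' independently. Map positions are reported in bp with 1 cM = 1e6 bp.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `ped` (a `pedigree`: all parents then all offspring),
#'   `geno` (a `genotype_matrix` for every animal, parents included) and
#'   `founder_freq` (the per-SNP founder allele frequencies).
#' @export
simulate_families <- function(config, seed) {
  set.seed(seed)
  nf <- config$n_families; no <- config$offspring_per_family
  m <- config$n_snps; nc <- config$n_chromosomes
  L <- config$chromosome_length

  per_chrom <- rep(m %/% nc, nc)
  extra <- m %% nc
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(nc)), per_chrom)
  pos_m <- unlist(lapply(per_chrom, function(k)
    if (k == 1L) L / 2 else seq(0, L, length.out = k)))
  bp <- round(pos_m * 1e8) + 1
  snp_id <- sprintf("snp_%s_%04d", sub("^chr", "c", chrom),
                    unlist(lapply(per_chrom, seq_len)))
  map <- data.frame(snp_id = snp_id, chrom = chrom, bp = bp,
                    stringsAsFactors = FALSE)

  freq <- stats::runif(m, 0.1, 0.9)
  # adjacent recombination fractions; 0.5 across chromosome boundaries
  gap <- c(0, diff(pos_m))
  newchrom <- c(TRUE, chrom[-1L] != chrom[-m])
  rfrac <- 0.5 * (1 - exp(-2 * gap))
  rfrac[newchrom] <- 0.5

  sire_ids <- sprintf("fam%03d_s", seq_len(nf))
  dam_ids <- sprintf("fam%03d_d", seq_len(nf))
  off_ids <- as.vector(t(outer(seq_len(nf), seq_len(no),
                               function(f, o) sprintf("fam%03d_o%02d", f, o))))
  n_par <- 2L * nf; n_off <- nf * no

  par_h1 <- matrix(stats::rbinom(n_par * m, 1L, rep(freq, each = n_par)),
                   n_par, m)
  par_h2 <- matrix(stats::rbinom(n_par * m, 1L, rep(freq, each = n_par)),
                   n_par, m)

  gamete <- function(h1, h2) {
    sw <- stats::runif(m) < rfrac
    phase <- cumsum(sw) %% 2L          # first element randomised via rfrac=0.5
    ifelse(phase == 0L, h1, h2)
  }
  off_codes <- matrix(0L, n_off, m)
  for (f in seq_len(nf)) {
    si <- 2L * f - 1L; di <- 2L * f
    for (o in seq_len(no)) {
      g1 <- gamete(par_h1[si, ], par_h2[si, ])
      g2 <- gamete(par_h1[di, ], par_h2[di, ])
      off_codes[(f - 1L) * no + o, ] <- g1 + g2
    }
  }
  par_codes <- par_h1 + par_h2
  # parents interleaved sire/dam per family
  par_ids <- as.vector(rbind(sire_ids, dam_ids))
  codes <- rbind(par_codes, off_codes)
  rownames(codes) <- c(par_ids, off_ids)
  colnames(codes) <- map$snp_id

  ped <- pedigree_table(
    animal = c(par_ids, off_ids),
    sire = c(rep(NA, n_par), rep(sire_ids, each = no)),
    dam = c(rep(NA, n_par), rep(dam_ids, each = no)))

  list(ped = ped, geno = genotype_matrix(codes, map), founder_freq = freq)
}

# resolve the QTL table for a config: sample SNPs and set effect sizes in
# raw parameter units (multiples of the polygenic SD of the target trait)
resolve_qtl <- function(config, geno) {
  if (!is.null(config$qtl_spec)) return(config$qtl_spec)
  if (config$qtl_per_param == 0L)
    return(data.frame(param = character(0), snp_id = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE))
  params <- c("A", "b", "K")
  sd_u <- sqrt(pmax(diag(config$polygenic_cov), 0))
  do.call(rbind, lapply(seq_along(params), function(j) {
    snps <- sample(geno$map$snp_id, config$qtl_per_param)
    eff <- sd_u[j] * c(config$large_effect_sd,
                       rep(config$small_effect_sd,
                           config$qtl_per_param - 1L))
    data.frame(param = params[j], snp_id = snps, effect = eff,
               size_class = c("large", rep("small",
                                           config$qtl_per_param - 1L)),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate growth phenotypes over a pedigree and genotypes
#'
#' Each animal's curve parameters are the population means plus the summed
#' QTL dosage effects, a polygenic deviation drawn from
#' `N(0, polygenic_cov (x) A)` with `A` the pedigree relationship matrix,
#' and (if configured) independent parameter noise. Weights are the
#' growth-model prediction at the configured ages plus
#' `N(0, residual_sd^2)` noise. The phenotyped animals are the first
#' `phenotyped_per_family` offspring of each family.
#'
#' @param ped A `pedigree` (from [simulate_families()]).
#' @param geno A `genotype_matrix`; genotyped animals must all appear in
#'   the pedigree.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `phenos` (list of [weight_series()] for the
#'   phenotyped animals), `truth` (list: `params` data.frame of per-animal
#'   true A/b/K, `qtl` table with positions merged in) and `qtl`.
#' @export
simulate_growth_phenotypes <- function(ped, geno, config, seed) {
  set.seed(seed)
  if (!all(geno$animal_ids %in% ped$animal))
    stop("genotyped animals must be a subset of the pedigree")
  qtl <- resolve_qtl(config, geno)

  off <- ped$animal[!is.na(ped$sire) | !is.na(ped$dam)]
  fam_of <- sub("_o[0-9]+$", "", off)
  keep <- unlist(lapply(split(off, fam_of), function(ids)
    utils::head(sort(ids), config$phenotyped_per_family)),
    use.names = FALSE)
  ids <- sort(keep)
  n <- length(ids)

  A <- build_a_matrix(ped)
  Asub <- rel_subset(A, ids)
  # polygenic draw: U = L_A Z L_S' with A = L_A L_A', Su = L_S L_S'
  eA <- eigen(sympart(Asub), symmetric = TRUE)
  LA <- eA$vectors %*% diag(sqrt(pmax(eA$values, 0)), n)
  eS <- eigen(config$polygenic_cov, symmetric = TRUE)
  LS <- eS$vectors %*% diag(sqrt(pmax(eS$values, 0)), 3)
  Z <- matrix(stats::rnorm(n * 3), n, 3)
  u <- LA %*% Z %*% t(LS)

  eE <- eigen(config$param_env_cov, symmetric = TRUE)
  LE <- eE$vectors %*% diag(sqrt(pmax(eE$values, 0)), 3)
  eps <- matrix(stats::rnorm(n * 3), n, 3) %*% t(LE)

  mu <- config$population_params[c("A", "b", "K")]
  par_mat <- matrix(rep(mu, each = n), n, 3,
                    dimnames = list(ids, c("A", "b", "K")))
  if (nrow(qtl) > 0) {
    W <- geno$codes[ids, , drop = FALSE]
    for (r in seq_len(nrow(qtl))) {
      dos <- W[, qtl$snp_id[r]]
      dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      par_mat[, qtl$param[r]] <- par_mat[, qtl$param[r]] +
        dos * qtl$effect[r]
    }
  }
  par_mat <- par_mat + u + eps
  # keep parameters in the model's admissible domain
  par_mat[, "A"] <- pmax(par_mat[, "A"], 1)
  par_mat[, "b"] <- pmax(par_mat[, "b"], 1e-6)
  par_mat[, "K"] <- pmax(par_mat[, "K"], 1e-6)

  tp <- config$time_points
  model <- growth_model(config$curve_model)
  phenos <- vector("list", n)
  for (i in seq_len(n)) {
    p <- c(A = par_mat[i, "A"], b = par_mat[i, "b"], K = par_mat[i, "K"])
    if (model$name == "richards")
      p <- c(p, M = unname(config$population_params["M"]))
    w <- predict_weight(model, p, tp) +
      stats::rnorm(length(tp), 0, config$residual_sd)
    phenos[[i]] <- weight_series(ids[i], tp, pmax(w, 1e-6),
                                 factors = list(family =
                                   sub("_o[0-9]+$", "", ids[i])))
  }
  if (nrow(qtl) > 0 && !("bp" %in% names(qtl)))
    qtl <- merge(qtl, geno$map, by = "snp_id", sort = FALSE)
  truth <- list(params = data.frame(animal = ids, par_mat,
                                    stringsAsFactors = FALSE,
                                    row.names = NULL),
                qtl = qtl)
  list(phenos = phenos, truth = truth, qtl = qtl)
}

#' Permute records across animals within each time point
#'
#' Implements the within-timepoint record shuffle: for every time point
#' independently, the weights are redistributed across animals by a
#' uniform random permutation, so each animal's new trajectory is
#' assembled from records of (generally) different animals measured at the
#' right ages. Per-timepoint marginal distributions are preserved exactly;
#' dependence across time points (and any genotype-phenotype link) is
#' destroyed, which makes the permuted data a null reference set.
#'
#' @param phenos List of [weight_series()] sharing identical time points.
#' @param seed Integer seed.
#' @return The permuted collection; factor levels stay with the animal.
#' @export
permute_within_timepoint <- function(phenos, seed) {
  set.seed(seed)
  wm <- weights_matrix(phenos)     # errors on ragged time points
  n <- nrow(wm)
  for (j in seq_len(ncol(wm))) wm[, j] <- wm[sample.int(n), j]
  out <- phenos
  for (i in seq_len(n)) out[[i]]$weights <- unname(wm[i, ])
  out
}
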