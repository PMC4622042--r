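#!/usr/bin/env Rscript
# Build the two study populations and write them out as flat files.
#
#   * cattle-like cohort: 1,255 animals in 251 full-sib families, Brody
#     growth at 0/6/12/15/18/24 months, polygenic (A, b, K) architecture
#     with the target heritabilities/correlations, no major QTL;
#   * multi-family validation population: 100 full-sib families x 20
#     offspring (half phenotyped), logistic growth at 5 time points,
#     453 SNPs on 5 chromosomes of 1 Morgan, 6 QTL per curve parameter.
#
# Downstream scripts (02-05) read everything from results/data/.

suppressMessages(library(gcgwas))
seed <- 20260921L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("-- cattle-like cohort --")
cfg <- sim_preset("brahman_like")
fam <- simulate_families(cfg, seed)
sim <- simulate_growth_phenotypes(fam$ped, fam$geno, cfg, seed + 1L)
write_phenotypes(sim$phenos, file.path(out, "cattle_phenotypes_long.csv"),
                 layout = "long")
write_pedigree(fam$ped, file.path(out, "cattle_pedigree.csv"))
utils::write.table(sim$truth$params, file.path(out, "cattle_truth.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("  ", length(sim$phenos), " phenotyped animals, ",
        nrow(fam$ped), " pedigree records")

message("-- multi-family validation population --")
cfgq <- sim_preset("qtlmas2009")
famq <- simulate_families(cfgq, seed + 2L)
simq <- simulate_growth_phenotypes(famq$ped, famq$geno, cfgq, seed + 3L)
write_phenotypes(simq$phenos, file.path(out, "qtlmas_phenotypes_long.csv"),
                 layout = "long")
write_pedigree(famq$ped, file.path(out, "qtlmas_pedigree.csv"))
write_genotypes(famq$geno, file.path(out, "qtlmas_genotypes.tsv"),
                file.path(out, "qtlmas_map.tsv"))
utils::write.table(simq$qtl, file.path(out, "qtlmas_qtl_truth.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("  ", length(simq$phenos), " phenotyped animals, ",
        ncol(famq$geno$codes), " SNPs, ", nrow(simq$qtl), " planted QTL")
message("done; files under ", out)
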