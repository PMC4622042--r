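#' Read a weight-age phenotype table
#'
#' Two layouts are supported. `"s1_wide"` has one row per animal with columns
#' `animal, sire, dam` followed by any categorical fixed-effect columns and
#' one `wt<age>` column per age (e.g. `wt0, wt6, wt12, wt15, wt18, wt24`).
#' `"long"` has one row per animal-age with columns `animal, age, weight`
#' plus factor columns repeated on every row. Animals with any missing
#' weight are returned flagged incomplete: the study design keeps only
#' animals with a full set of records, but the raw rows are preserved so
#' the exclusion happens downstream, visibly.
#'
#' @param path CSV file path.
#' @param layout `"s1_wide"` or `"long"`.
#' @return List of [weight_series()], one per animal.
#' @export
read_phenotypes <- function(path, layout = c("s1_wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (layout == "s1_wide") {
    wt_cols <- grep("^wt[0-9.]+$", names(df), value = TRUE)
    if (length(wt_cols) == 0L)
      stop("no weight columns (wt<age>) found in ", path)
    ages <- as.numeric(sub("^wt", "", wt_cols))
    wt_cols <- wt_cols[order(ages)]; ages <- sort(ages)
    fac_cols <- setdiff(names(df), c("animal", "sire", "dam", wt_cols))
    if (anyDuplicated(df$animal)) {
      dup <- df$animal[duplicated(df$animal)]
      sub <- df[df$animal %in% dup, wt_cols, drop = FALSE]
      if (nrow(unique(cbind(df$animal[df$animal %in% dup], sub))) !=
          length(unique(dup)))
        stop("duplicate animal with conflicting weights: ",
             paste(unique(dup), collapse = ", "))
      df <- df[!duplicated(df$animal), , drop = FALSE]
    }
    out <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      wraw <- df[i, wt_cols]
      wnum <- suppressWarnings(as.numeric(wraw))
      bad <- !is.na(wraw) & wraw != "" & is.na(wnum)
      if (any(bad))
        stop("malformed weight '", wraw[bad][1L], "' at line ", i + 1L,
             " of ", path)
      miss <- is.na(wnum) | wraw == ""
      out[[i]] <- weight_series(
        animal_id = df$animal[i],
        ages = ages[!miss], weights = wnum[!miss],
        factors = as.list(df[i, fac_cols, drop = FALSE]),
        complete = !any(miss))
    }
    return(out)
  }
  # long layout
  need <- c("animal", "age", "weight")
  if (!all(need %in% names(df)))
    stop("long layout needs columns animal, age, weight in ", path)
  age <- suppressWarnings(as.numeric(df$age))
  wt <- suppressWarnings(as.numeric(df$weight))
  bad <- which(is.na(age) | (is.na(wt) & df$weight != "" & !is.na(df$weight)))
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path)
  fac_cols <- setdiff(names(df), need)
  ids <- unique(df$animal)
  lapply(ids, function(id) {
    rows <- which(df$animal == id)
    o <- rows[order(age[rows])]
    if (anyDuplicated(age[o]))
      stop("duplicate animal-age with conflicting weights for ", id)
    miss <- is.na(wt[o])
    weight_series(id, age[o][!miss], wt[o][!miss],
                  factors = as.list(df[o[1L], fac_cols, drop = FALSE]),
                  complete = !any(miss))
  })
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]; `read(write(x))` round-trips.
#'
#' @param phenos List of [weight_series()].
#' @param path Output CSV path.
#' @param layout `"s1_wide"` (requires a shared age grid) or `"long"`.
#' @export
write_phenotypes <- function(phenos, path, layout = c("s1_wide", "long")) {
  layout <- match.arg(layout)
  fac_names <- names(phenos[[1L]]$factors)
  if (layout == "s1_wide") {
    ages <- sort(unique(unlist(lapply(phenos, function(w) w$ages))))
    rows <- lapply(phenos, function(w) {
      wt <- stats::setNames(rep(NA_real_, length(ages)),
                            paste0("wt", ages))
      wt[paste0("wt", w$ages)] <- w$weights
      c(list(animal = w$animal_id, sire = "0", dam = "0"),
        lapply(w$factors, as.character), as.list(wt))
    })
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    df <- do.call(rbind, lapply(phenos, function(w) {
      base <- data.frame(animal = w$animal_id, age = w$ages,
                         weight = w$weights, stringsAsFactors = FALSE)
      for (nm in fac_names) base[[nm]] <- as.character(w$factors[[nm]])
      base
    }))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Read a three-column pedigree CSV
#'
#' Columns `animal, sire, dam`; unknown parents coded `0`, `NA` or empty.
#' The result is sorted topologically (every parent's row precedes all of
#' its offspring's rows); a cycle (an animal that is its own ancestor) is an
#' error naming the animals involved.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `pedigree` with character columns
#'   `animal`, `sire`, `dam` (`NA` = unknown), topologically sorted.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df)[1:3] <- c("animal", "sire", "dam")
  pedigree_table(df$animal, df$sire, df$dam)
}

#' Construct and topologically sort a pedigree table
#'
#' @param animal,sire,dam Character vectors; unknown parents `"0"`, `""` or
#'   `NA`.
#' @return Sorted `pedigree` data.frame; see [read_pedigree()].
#' @export
pedigree_table <- function(animal, sire, dam) {
  clean <- function(x) {
    x <- as.character(x); x[x %in% c("0", "") | is.na(x)] <- NA_character_; x
  }
  animal <- as.character(animal); sire <- clean(sire); dam <- clean(dam)
  if (anyDuplicated(animal))
    stop("duplicate animal ids in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  # parents referenced but never listed become implicit founders
  known <- c(sire, dam)
  extra <- setdiff(known[!is.na(known)], animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(animal)
  idx <- stats::setNames(seq_len(n), animal)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  # Kahn's algorithm over parent -> offspring edges
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stop("pedigree cycle detected involving: ",
         paste(animal[setdiff(seq_len(n), ord)], collapse = ", "))
  out <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Write a pedigree CSV (inverse of [read_pedigree()])
#' @param ped A `pedigree` data.frame.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"; df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a biallelic SNP genotype matrix with its map
#'
#' Genotypes are allele dosages: 0 for the homozygote of the first allele,
#' 1 for the heterozygote, 2 for the homozygote of the second allele;
#' missing is explicit (`NA`), never conflated with 0. Two dialects:
#' `"tsv012"` is a TSV with an `animal` column and one 0/1/2/NA column per
#' SNP; `"plink_raw"` is the PLINK `--recode A` text layout (header
#' `FID IID PAT MAT SEX PHENOTYPE snp_<allele> ...`, whitespace separated).
#' The map is a TSV with columns `snp_id, chrom, bp` (1-based). SNPs are
#' returned sorted by (chromosome, bp).
#'
#' @param geno_path Genotype file path.
#' @param map_path Map TSV path.
#' @param dialect `"tsv012"` or `"plink_raw"`.
#' @return A `genotype_matrix`: list with `codes` (integer matrix animals x
#'   SNPs, `NA` for missing), `animal_ids`, `map` (data.frame `snp_id,
#'   chrom, bp`) and `alleles` (per-SNP counted-allele label or `NA`).
#' @export
read_genotypes <- function(geno_path, map_path,
                           dialect = c("tsv012", "plink_raw")) {
  dialect <- match.arg(dialect)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  names(map)[1:3] <- c("snp_id", "chrom", "bp")
  if (any(map$bp < 0)) stop("negative bp position in map: ", map_path)
  if (dialect == "tsv012") {
    df <- utils::read.delim(geno_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    ids <- as.character(df[[1L]])
    codes <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(codes) <- "integer"
    alleles <- rep(NA_character_, ncol(codes))
  } else {
    df <- utils::read.table(geno_path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE, na.strings = c("NA", "-9"))
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)))
      stop("plink_raw header must contain ", paste(meta, collapse = " "))
    ids <- as.character(df$IID)
    snp_cols <- setdiff(names(df), meta)
    codes <- as.matrix(df[, snp_cols, drop = FALSE])
    storage.mode(codes) <- "integer"
    alleles <- sub("^.*_", "", snp_cols)
    colnames(codes) <- sub("_[^_]*$", "", snp_cols)
  }
  bad <- codes[!is.na(codes) & !(codes %in% 0:2)]
  if (length(bad))
    stop("genotype code outside {0,1,2}: ", bad[1L], " in ", geno_path)
  rownames(codes) <- ids
  missing_map <- setdiff(colnames(codes), map$snp_id)
  if (length(missing_map))
    stop("SNP(s) in genotype file absent from map: ",
         paste(utils::head(missing_map, 5L), collapse = ", "))
  map <- map[match(colnames(codes), map$snp_id), , drop = FALSE]
  ord <- order(map$chrom, map$bp)
  genotype_matrix(codes[, ord, drop = FALSE], map[ord, , drop = FALSE],
                  alleles[ord])
}

#' Construct a genotype_matrix object
#'
#' @param codes Integer matrix animals x SNPs in {0,1,2,NA}; rownames are
#'   animal ids, colnames SNP ids.
#' @param map Data frame `snp_id, chrom, bp` aligned with the columns.
#' @param alleles Optional per-SNP counted-allele labels.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, map, alleles = NULL) {
  stopifnot(ncol(codes) == nrow(map),
            all(colnames(codes) == map$snp_id))
  if (any(!is.na(codes) & !(codes %in% 0:2)))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (is.unsorted(bp)) stop("SNPs not sorted by bp within chromosome ", ch)
  }
  rownames(map) <- NULL
  structure(list(codes = codes, animal_ids = rownames(codes), map = map,
                 alleles = alleles %||% rep(NA_character_, nrow(map))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", nrow(x$codes), "animals x", ncol(x$codes),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a genotype matrix in the tsv012 dialect plus its map
#' @param geno A `genotype_matrix`.
#' @param geno_path,map_path Output paths.
#' @export
write_genotypes <- function(geno, geno_path, map_path) {
  df <- data.frame(animal = geno$animal_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(geno$codes, check.names = FALSE))
  utils::write.table(df, geno_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  utils::write.table(geno$map, map_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(geno_path)
}

#' Read a gene table from a BED file
#'
#' BED's 0-based half-open intervals are converted at the boundary to the
#' 1-based inclusive coordinates used everywhere inside the pipeline
#' (matching how SNP bp positions are quoted). Requires BED3+ with a name
#' column; strand is kept when present.
#'
#' @param path BED file path.
#' @return A `gene_table` data.frame: `gene_id, chrom, start, end, strand`,
#'   sorted by (chromosome, start), 1-based inclusive.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(gene_table(character(0), character(0), integer(0), integer(0)))
  gr <- rtracklayer::import(path, format = "BED")
  gene_table(
    gene_id = S4Vectors::mcols(gr)$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # rtracklayer already 1-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Construct a gene table (1-based inclusive coordinates)
#' @param gene_id,chrom Character vectors.
#' @param start,end Integer vectors, `start <= end`, 1-based inclusive.
#' @param strand Optional strand (`"+"`, `"-"`, `"*"`).
#' @return A `gene_table` data.frame sorted by (chrom, start).
#' @export
gene_table <- function(gene_id, chrom, start, end, strand = NULL) {
  if (any(start > end)) stop("gene with start > end")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = if (is.null(strand)) rep("*", length(gene_id))
                            else as.character(strand),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Write a gene table back to BED (inverse of [read_gene_table()])
#' @param genes A `gene_table`.
#' @param path Output BED path.
#' @export
write_gene_table <- function(genes, path) {
  if (nrow(genes) == 0L) { file.create(path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$name <- genes$gene_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
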