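#' Pedigree additive (numerator) relationship matrix
#'
#' Henderson's tabular method over a topologically sorted pedigree:
#' `a_ii = 1 + a_{sd}/2` (the parents' relationship halved measures the
#' animal's inbreeding) and `a_ij = (a_{j,sire(i)} + a_{j,dam(i)}) / 2` for
#' `j < i`, with unknown parents contributing 0. Founders get diagonal 1.
#' Dense construction; intended for pedigrees up to a few tens of thousands
#' of animals.
#'
#' @param ped A `pedigree` data.frame from [read_pedigree()] /
#'   [pedigree_table()] (parents before offspring).
#' @return Symmetric numeric matrix with animal ids as dimnames.
#' @export
build_a_matrix <- function(ped) {
  animal <- ped$animal
  n <- length(animal)
  idx <- stats::setNames(seq_len(n), animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE))
    stop("pedigree is not sorted parents-first; use pedigree_table()")
  A <- matrix(0, n, n, dimnames = list(animal, animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0L) A[s, j] else 0) +
                    (if (d > 0L) A[d, j] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Principal submatrix of a relationship matrix
#'
#' Extracts the block for a subset of animals in the requested order. The
#' GWAS works on the phenotyped subset of a relationship matrix computed
#' from the full pedigree, so ancestors contribute relationships without
#' entering the mixed-model equations. A principal submatrix of a PSD
#' matrix is PSD, so the subset remains a valid covariance kernel.
#'
#' @param rel Relationship matrix with id dimnames.
#' @param ids Character vector, subset of `rownames(rel)`.
#' @return The submatrix in the order of `ids`.
#' @export
rel_subset <- function(rel, ids) {
  unknown <- setdiff(ids, rownames(rel))
  if (length(unknown))
    stop("id(s) not in relationship matrix: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  rel[ids, ids, drop = FALSE]
}

#' Dump a relationship matrix as TSV (ids header + rows), for debugging
#' @param rel Relationship matrix.
#' @param path Output path.
#' @export
write_relationship <- function(rel, path) {
  utils::write.table(data.frame(animal = rownames(rel), rel,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
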