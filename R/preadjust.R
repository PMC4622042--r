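#' Pre-adjust weight records for fixed effects, one age at a time
#'
#' For each age independently, fits an ordinary least-squares model of
#' weight on the named categorical factors and replaces each record by the
#' grand mean at that age plus the animal's residual. This removes
#' management/cohort effects (contemporary group, birth year/month/day,
#' farm codes) from the raw weights before any growth curve is fitted,
#' because those effects act on the observed weights, not on the curve
#' parameters. A factor level observed on a single animal contributes a
#' zero residual (OLS fits it exactly), and the grand mean at each age is
#' left unchanged.
#'
#' @param phenos List of [weight_series()] sharing one age grid.
#' @param factor_names Character vector naming entries of each series'
#'   `factors` list to adjust for. Empty vector returns the input unchanged.
#' @return The collection with adjusted weights; factor levels retained.
#' @export
preadjust_fixed_effects <- function(phenos, factor_names) {
  if (length(factor_names) == 0L) return(phenos)
  ages <- shared_ages(phenos)
  n <- length(phenos)
  if (n < 2L) stop("need at least 2 animals per fitted age")
  fac <- lapply(factor_names, function(nm) {
    lv <- vapply(phenos, function(w) {
      if (is.null(w$factors[[nm]]))
        stop("animal ", w$animal_id, " has no level for factor '", nm, "'")
      as.character(w$factors[[nm]])
    }, character(1L))
    factor(lv)
  })
  names(fac) <- factor_names
  # a factor with a single level adjusts nothing; drop it from the model
  fac <- Filter(function(f) nlevels(f) >= 2L, fac)
  if (length(fac) == 0L) return(phenos)
  df <- as.data.frame(fac, stringsAsFactors = TRUE)
  wm <- weights_matrix(phenos)

  adj <- wm
  for (j in seq_along(ages)) {
    df$weight <- wm[, j]
    ft <- stats::lm(weight ~ ., data = df)
    if (ft$df.residual == 0L)
      stop("fixed effects perfectly confounded with animals at age ",
           ages[j], ": no residual degrees of freedom")
    adj[, j] <- mean(wm[, j]) + stats::residuals(ft)
  }
  out <- phenos
  for (i in seq_len(n)) {
    out[[i]]$weights <- unname(adj[i, ])
    if (any(out[[i]]$weights <= 0))
      out[[i]]$weights <- pmax(out[[i]]$weights, 1e-6)
  }
  out
}
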