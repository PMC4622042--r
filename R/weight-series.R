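#' One animal's weight-age series
#'
#' The raw phenotype unit of the pipeline: an ordered set of (age, weight)
#' records for a single animal plus the categorical fixed-effect levels
#' (contemporary group, birth year/month/day, farm codes) attached to it.
#'
#' @param animal_id Character scalar, unique animal identifier.
#' @param ages Numeric vector of ages, strictly increasing. Months for the
#'   cattle design (0, 6, 12, 15, 18, 24); the simulator may use days.
#' @param weights Numeric vector of body weights (kg), positive and finite,
#'   same length as `ages`.
#' @param factors Named list of fixed-effect factor levels (each a scalar).
#' @param complete Logical; `FALSE` flags an animal whose original record had
#'   missing weights (such animals are excluded from fitting by default).
#' @return An object of class `weight_series`.
#' @export
weight_series <- function(animal_id, ages, weights, factors = list(),
                          complete = TRUE) {
  stopifnot(is.character(animal_id), length(animal_id) == 1L)
  ages <- as.numeric(ages)
  weights <- as.numeric(weights)
  if (length(ages) != length(weights))
    stop("ages and weights must have the same length for animal ", animal_id)
  if (length(ages) > 1L && any(diff(ages) <= 0))
    stop("ages must be strictly increasing for animal ", animal_id)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite for animal ", animal_id)
  structure(
    list(animal_id = animal_id, ages = ages, weights = weights,
         factors = factors, complete = isTRUE(complete)),
    class = "weight_series"
  )
}

#' @export
print.weight_series <- function(x, ...) {
  cat("<weight_series>", x$animal_id,
      if (!x$complete) "(incomplete)" else "", "\n")
  print(stats::setNames(x$weights, x$ages))
  invisible(x)
}

#' Ages shared by a collection of weight series
#'
#' @param phenos List of [weight_series()] objects.
#' @return The common age grid; errors if the animals' grids differ (ragged).
#' @keywords internal
shared_ages <- function(phenos) {
  ages <- phenos[[1L]]$ages
  same <- vapply(phenos, function(w) {
    length(w$ages) == length(ages) && all(w$ages == ages)
  }, logical(1L))
  if (!all(same))
    stop("animals do not share identical time points (ragged series)")
  ages
}

#' Stack a collection of weight series into a matrix
#'
#' @param phenos List of [weight_series()] sharing one age grid.
#' @return Numeric matrix animals x ages, rownames animal ids.
#' @export
weights_matrix <- function(phenos) {
  ages <- shared_ages(phenos)
  m <- do.call(rbind, lapply(phenos, function(w) w$weights))
  rownames(m) <- vapply(phenos, function(w) w$animal_id, character(1L))
  colnames(m) <- as.character(ages)
  m
}
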